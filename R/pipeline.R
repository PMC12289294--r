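#' Run the full analysis pipeline on a corpus
#'
#' Applies the study inclusion filters (date, country, exact-duplicate
#' removal), annotates each retained post with its drug category and
#' adverse-event set, and computes the frequency table, the
#' any-adverse-event share, the monthly trend series, and the
#' co-occurrence network with Louvain communities, edge tiers, and a
#' seeded spring layout.
#'
#' @param posts a post tibble (e.g. from [read_corpus()] or
#'   [generate_corpus()]).
#' @param filter a [corpus_filter()].
#' @param lexicon an [load_lexicon()] object.
#' @param seed seed for community detection and layout.
#' @param min_edge_weight minimum co-occurrence count for an edge.
#' @param layout_k,layout_iterations spring layout parameters.
#' @param monthly_mode `"mention_sum"` or `"distinct_posts"`.
#' @return an object of class `ae_report`: list with `filter_report`,
#'   `annotated`, `freq_table`, `ae_share`, `monthly`, `graph`,
#'   `partition`, `layout`, `tiers`, and `config` (seed, parameters,
#'   lexicon checksums).
#' @export
run_pipeline <- function(posts, filter = corpus_filter(),
                         lexicon = load_lexicon(), seed = 0,
                         min_edge_weight = 1, layout_k = 7.8,
                         layout_iterations = 100,
                         monthly_mode = "mention_sum") {
  fc <- filter_corpus(posts, filter)
  annotated <- annotate_corpus(fc$posts, lexicon)
  if (nrow(annotated) == 0) {
    ae_abort("no analyzable posts after filtering and annotation",
             "aeminer_empty_corpus_error")
  }
  ft <- frequency_table(annotated, lexicon)
  share <- ae_share_of_total(annotated)
  monthly <- monthly_series(annotated, mode = monthly_mode,
                            start = filter$start_date,
                            end = filter$end_date)
  graph <- build_cooccurrence(annotated, min_weight = min_edge_weight)
  partition <- NULL
  layout <- NULL
  tiers <- NULL
  if (nrow(graph$edges) > 0) {
    partition <- louvain(graph, seed = seed)
    layout <- spring_layout(graph, k = layout_k,
                            iterations = layout_iterations, seed = seed)
    tiers <- tier_edges(graph)
  }
  structure(
    list(filter_report = fc$report, annotated = annotated, freq_table = ft,
         ae_share = share, monthly = monthly, graph = graph,
         partition = partition, layout = layout, tiers = tiers,
         config = list(seed = seed, min_edge_weight = min_edge_weight,
                       layout_k = layout_k,
                       layout_iterations = layout_iterations,
                       monthly_mode = monthly_mode,
                       filter = unclass(filter),
                       lexicon_checksums = lexicon$checksums)),
    class = "ae_report")
}

#' @export
print.ae_report <- function(x, ...) {
  r <- x$filter_report
  cat("Adverse-event mention report\n")
  cat(sprintf("  posts: %d read, %d in window, %d after dedup, %d annotated\n",
              r$n_input, r$n_after_date, r$n_after_dedup, nrow(x$annotated)))
  cat(sprintf("  posts mentioning adverse events: %d (%.1f%%)\n",
              x$ae_share$n_ae_posts, x$ae_share$pct))
  if (!is.null(x$partition)) {
    cat(sprintf("  network: %d nodes, %d edges, %d communities, Q = %.4f\n",
                nrow(x$graph$nodes), nrow(x$graph$edges),
                length(unique(x$partition$membership)),
                x$partition$modularity))
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits the filter report (JSON), the frequency table (long and wide
#' CSV), the monthly series (CSV, with the key events alongside), the
#' network (GraphML + TSV edge list), the community partition (JSON), the
#' layout coordinates (CSV), and a run manifest (seed, parameters, lexicon
#' checksums). All outputs are plain text and byte-stable under a fixed
#' config and seed. Each table is re-read after writing as a schema check.
#'
#' @param report an [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @param figures also render the time-series and network PNG figures.
#' @return the directory, invisibly.
#' @export
write_report_bundle <- function(report, dir, figures = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(dir, f)

  jsonlite::write_json(unclass(report$filter_report),
                       path("filter_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  readr::write_csv(report$freq_table$cells, path("frequency_table_long.csv"),
                   progress = FALSE)
  readr::write_csv(frequency_table_wide(report$freq_table),
                   path("frequency_table_wide.csv"), progress = FALSE)
  readr::write_csv(report$freq_table$drug_totals, path("drug_totals.csv"),
                   progress = FALSE)
  monthly <- as_tibble(report$monthly)
  readr::write_csv(monthly, path("monthly_series.csv"), progress = FALSE)
  readr::write_csv(attr(report$monthly, "key_events"), path("key_events.csv"),
                   progress = FALSE)
  if (!is.null(report$partition)) {
    write_graphml(report$graph, path("cooccurrence.graphml"),
                  membership = report$partition$membership)
    write_edge_list(report$graph, path("edges.tsv"))
    jsonlite::write_json(
      list(membership = as.list(report$partition$membership),
           modularity = report$partition$modularity),
      path("partition.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
    readr::write_csv(report$layout, path("layout.csv"), progress = FALSE)
  }
  jsonlite::write_json(
    list(seed = report$config$seed,
         min_edge_weight = report$config$min_edge_weight,
         layout_k = report$config$layout_k,
         layout_iterations = report$config$layout_iterations,
         monthly_mode = report$config$monthly_mode,
         filter = lapply(report$config$filter, as.character),
         lexicon_checksums = as.list(report$config$lexicon_checksums),
         n_annotated = nrow(report$annotated)),
    path("manifest.json"), auto_unbox = TRUE, pretty = TRUE)

  # schema check: every table must re-read with the expected columns
  stopifnot(
    all(c("ae_category", "ae_id", "category_id", "n", "pct") %in%
          names(readr::read_csv(path("frequency_table_long.csv"),
                                show_col_types = FALSE, progress = FALSE))),
    all(c("month", "n_drug_posts", "n_ae_mentions", "pct") %in%
          names(readr::read_csv(path("monthly_series.csv"),
                                show_col_types = FALSE, progress = FALSE)))
  )

  if (figures) {
    ggplot2::ggsave(path("time_series.png"), plot_monthly_series(report$monthly),
                    width = 9, height = 4.5, dpi = 150)
    if (!is.null(report$partition)) {
      ggplot2::ggsave(path("network.png"),
                      plot_cooccurrence_network(report$graph, report$layout,
                                                report$partition),
                      width = 7.5, height = 6.5, dpi = 150)
    }
  }
  invisible(dir)
}
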