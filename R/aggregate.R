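#' Per-drug adverse-event frequency and percentage table
#'
#' Counts, for every (drug category, adverse event) pair, the distinct
#' posts mentioning the event, with the percentage over the drug's post
#' total (half-up rounding, 2 decimals). Rows are grouped by
#' adverse-event category; blocks and rows within a block are ordered by
#' descending reference column (default: the corpus-wide mention total),
#' reproducing the published layout convention.
#'
#' @param annotated an annotated corpus from [annotate_corpus()].
#' @param lexicon the lexicon defining the adverse-event taxonomy.
#' @param order_by `"total"` (corpus-wide mention count) or a drug
#'   `category_id` whose column orders the rows.
#' @return an object of class `ae_frequency_table`: list with
#'   `cells` (long tibble `ae_category`, `ae_id`, `category_id`, `n`,
#'   `pct`), `drug_totals` (`category_id`, `total_posts`,
#'   `total_ae_mentions`), and `ae_totals` (`ae_id`, `n_total`). Cells for
#'   drug categories with zero posts carry `pct = NA` (undefined), never
#'   NaN.
#' @export
frequency_table <- function(annotated, lexicon = load_lexicon(),
                            order_by = "total") {
  ae_tax <- dplyr::distinct(lexicon$aes[, c("ae_id", "ae_category")])
  drugs <- drug_categories()

  mentions <- tibble(
    category_id = rep(annotated$drug_category, lengths(annotated$ae_ids)),
    ae_id = unlist(annotated$ae_ids, use.names = FALSE)
  )
  counts <- mentions |> count(.data$category_id, .data$ae_id)

  totals <- annotated |>
    count(category_id = .data$drug_category, name = "total_posts") |>
    tidyr::complete(category_id = drugs, fill = list(total_posts = 0L))

  cells <- tidyr::expand_grid(ae_id = ae_tax$ae_id, category_id = drugs) |>
    left_join(counts, by = c("ae_id", "category_id")) |>
    mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    left_join(totals, by = "category_id") |>
    mutate(pct = pct_cell(.data$n, .data$total_posts)) |>
    left_join(ae_tax, by = "ae_id")

  ae_totals <- cells |>
    group_by(.data$ae_id) |>
    summarise(n_total = sum(.data$n), .groups = "drop")

  key <- if (identical(order_by, "total")) {
    ae_totals |> rename(order_n = "n_total")
  } else {
    stopifnot(order_by %in% drugs)
    cells |> filter(.data$category_id == order_by) |>
      select("ae_id", order_n = "n")
  }
  cells <- cells |>
    left_join(key, by = "ae_id") |>
    group_by(.data$ae_category) |>
    mutate(block_n = sum(.data$n)) |>
    ungroup() |>
    arrange(desc(.data$block_n), .data$ae_category, desc(.data$order_n),
            .data$ae_id, factor(.data$category_id, levels = drugs)) |>
    select("ae_category", "ae_id", "category_id", "n", "total_posts", "pct")

  drug_totals <- cells |>
    group_by(.data$category_id) |>
    summarise(total_posts = .data$total_posts[1],
              total_ae_mentions = sum(.data$n), .groups = "drop") |>
    arrange(factor(.data$category_id, levels = drugs))

  structure(list(cells = cells, drug_totals = drug_totals,
                 ae_totals = ae_totals),
            class = "ae_frequency_table")
}

#' @export
print.ae_frequency_table <- function(x, ...) {
  cat("Adverse-event frequency table:",
      nrow(x$ae_totals), "adverse events x",
      nrow(x$drug_totals), "drug categories\n")
  cat("Posts per category:\n")
  print(as.data.frame(x$drug_totals), row.names = FALSE)
  invisible(x)
}

#' Wide (published-layout) view of a frequency table
#'
#' @param ft an [frequency_table()] result.
#' @param value `"n"`, `"pct"`, or `"label"` (`"n (pct)"` cells).
#' @return wide tibble, one row per adverse event, one column per drug.
#' @export
frequency_table_wide <- function(ft, value = c("label", "n", "pct")) {
  value <- match.arg(value)
  cells <- ft$cells
  cells$cell <- switch(value,
    n = as.character(cells$n),
    pct = sprintf("%.2f", cells$pct),
    label = sprintf("%d (%.2f)", cells$n, cells$pct))
  tidyr::pivot_wider(cells, id_cols = c("ae_category", "ae_id"),
                     names_from = "category_id", values_from = "cell")
}

#' Share of posts mentioning at least one adverse event
#'
#' @param annotated an annotated corpus.
#' @return list with `n_ae_posts`, `n_posts`, and `pct` (1 decimal,
#'   half-up).
#' @export
ae_share_of_total <- function(annotated) {
  n_ae <- sum(lengths(annotated$ae_ids) > 0)
  n <- nrow(annotated)
  list(n_ae_posts = n_ae, n_posts = n,
       pct = if (n > 0) pct_cell(n_ae, n, digits = 1) else NA_real_)
}

#' Monthly adverse-event mention series with key-event annotation
#'
#' Aggregates the annotated corpus by calendar month over a contiguous
#' month range (zero months emitted as zeros). Two senses of "frequency of
#' adverse events" are supported: `mention_sum` (sum over posts of
#' adverse-event set sizes; the default) and `distinct_posts` (posts
#' mentioning at least one adverse event).
#'
#' @param annotated an annotated corpus.
#' @param mode `"mention_sum"` or `"distinct_posts"`.
#' @param start,end optional dates bounding the month range; default the
#'   corpus's own span.
#' @param key_events tibble of `(date, label)` markers attached for
#'   plotting and reporting.
#' @return tibble of class `monthly_series` with `month` ("YYYY-MM"),
#'   `n_drug_posts`, `n_ae_mentions`, `pct` (`NA` where the month has no
#'   posts); key events in attribute `key_events`.
#' @export
monthly_series <- function(annotated,
                           mode = c("mention_sum", "distinct_posts"),
                           start = NULL, end = NULL,
                           key_events = default_key_events()) {
  mode <- match.arg(mode)
  stopifnot(nrow(annotated) > 0 || (!is.null(start) && !is.null(end)))
  first <- as.Date(start %||% min(annotated$date))
  last <- as.Date(end %||% max(annotated$date))
  months <- format(seq(as.Date(format(first, "%Y-%m-01")),
                       as.Date(format(last, "%Y-%m-01")), by = "month"),
                   "%Y-%m")
  per_post <- tibble(
    month = format(annotated$date, "%Y-%m"),
    n_ae = if (mode == "mention_sum") lengths(annotated$ae_ids)
           else as.integer(lengths(annotated$ae_ids) > 0)
  )
  out <- per_post |>
    group_by(.data$month) |>
    summarise(n_drug_posts = dplyr::n(), n_ae_mentions = sum(.data$n_ae),
              .groups = "drop") |>
    right_join(tibble(month = months), by = "month") |>
    arrange(.data$month) |>
    mutate(n_drug_posts = dplyr::coalesce(.data$n_drug_posts, 0L),
           n_ae_mentions = dplyr::coalesce(.data$n_ae_mentions, 0L),
           pct = pct_cell(.data$n_ae_mentions, .data$n_drug_posts))
  attr(out, "key_events") <- key_events
  attr(out, "mode") <- mode
  class(out) <- c("monthly_series", class(out))
  out
}
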