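#' Published per-drug adverse-event mention counts
#'
#' The published frequency table for the 2022-01 to 2024-05 Facebook study
#' corpus: for each of the 51 adverse events and 7 drug categories, the
#' number of posts mentioning the event and the percentage as printed.
#' These counts are inputs (the raw corpus is not redistributable): they
#' seed the synthetic generator's default per-drug mention rates and the
#' worked-example percentage checks.
#'
#' @return long tibble with `ae_id`, `category_id`, `n`, `printed_pct`,
#'   `total_posts`.
#' @export
reference_ae_counts <- function() {
  ref <- readr::read_csv(
    system.file("extdata", "ae_reference_counts.csv", package = "aeminer"),
    col_types = readr::cols(ae_id = "c", .default = "d"), progress = FALSE)
  tot <- reference_drug_totals()
  ref |>
    tidyr::pivot_longer(-"ae_id", names_to = c(".value", "category_id"),
                        names_pattern = "(n|pct)_(.*)") |>
    rename(printed_pct = "pct") |>
    left_join(tot[, c("category_id", "total_posts")], by = "category_id")
}

#' Published per-drug post totals
#'
#' Post counts per drug category after duplicate removal (the seven counts
#' sum exactly to the 59,293-post corpus), plus the published total
#' adverse-event mention sums per category.
#'
#' @return tibble with `category_id`, `total_posts`, `total_ae_mentions`.
#' @export
reference_drug_totals <- function() {
  readr::read_csv(
    system.file("extdata", "drug_totals.csv", package = "aeminer"),
    col_types = "cii", progress = FALSE)
}

#' Key events annotated on the temporal trend series
#'
#' Four regulatory/media milestones in the study window that temporal
#' mention trends are read against. Shipped as data, editable by the user.
#'
#' @return tibble with `date` (Date) and `label`.
#' @export
default_key_events <- function() {
  readr::read_csv(
    system.file("extdata", "key_events.csv", package = "aeminer"),
    col_types = "Dc", progress = FALSE)
}

#' Default planted co-mention clusters
#'
#' The three published co-occurrence communities (27 adverse events): a
#' somatic/metabolic cluster, a neurological/inflammatory-discomfort
#' cluster, and a gastrointestinal-distress cluster. Used as the synthetic
#' generator's default `clusters`.
#'
#' @return named list of character vectors of `ae_id`s.
#' @export
default_clusters <- function() {
  df <- readr::read_csv(
    system.file("extdata", "ae_clusters.csv", package = "aeminer"),
    col_types = "ci", progress = FALSE)
  split(df$ae_id, paste0("cluster", df$cluster))
}
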