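#' Read a CrowdTangle-style post export
#'
#' Reads a public-post export in the CrowdTangle CSV dialect (header row
#' with columns `Message`, `Date`, `Page Name`, `Page Admin Top Country`,
#' `Likes`, `Comments`, `Shares`, `Views`) or its JSONL mirror with
#' snake_case keys. Dates may be `YYYY-MM-DD` or `YYYY-MM-DD HH:MM:SS`;
#' only the day is retained. Missing optional columns default (engagement
#' counts to 0, page name to `""`); `message`, `date` and
#' `page_admin_country` are required.
#'
#' @param path path to the corpus file.
#' @param format `"csv"` or `"jsonl"`.
#' @param column_map named character vector overriding the default CSV
#'   header spellings, e.g. `c(message = "Post Text")`.
#' @return a tibble of posts, one row per input row in file order, with
#'   columns `post_id`, `message`, `date` (`Date`), `page_name`,
#'   `page_admin_country`, `likes`, `comments`, `shares`, `views`.
#' @export
read_corpus <- function(path, format = c("csv", "jsonl"), column_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    ae_abort(paste0("corpus file not found: ", path), "aeminer_io_error")
  }
  if (format == "csv") {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    map <- ct_column_map(column_map)
    missing <- setdiff(c("message", "date", "page_admin_country"),
                       names(map)[map %in% names(raw)])
    if (length(missing) > 0) {
      ae_abort(paste0("corpus is missing required column(s): ",
                      paste(map[missing], collapse = ", ")),
               "aeminer_schema_error")
    }
    get <- function(field, default = NULL) {
      col <- map[[field]]
      if (!is.null(col) && col %in% names(raw)) raw[[col]] else default
    }
    n <- nrow(raw)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, jsonlite::fromJSON)
    n <- length(rows)
    field_names <- unique(unlist(lapply(rows, names)))
    missing <- setdiff(c("message", "date", "page_admin_country"), field_names)
    if (length(missing) > 0) {
      ae_abort(paste0("corpus is missing required column(s): ",
                      paste(missing, collapse = ", ")),
               "aeminer_schema_error")
    }
    get <- function(field, default = NULL) {
      vals <- lapply(rows, function(r) r[[field]])
      if (all(vapply(vals, is.null, logical(1)))) return(default)
      vapply(vals, function(v) if (is.null(v)) NA_character_ else as.character(v),
             character(1))
    }
  }
  int_col <- function(x) {
    if (is.null(x)) return(rep(0L, n))
    out <- suppressWarnings(as.integer(x))
    out[is.na(out)] <- 0L
    out
  }
  tibble(
    post_id = get("post_id", default = sprintf("row%06d", seq_len(n))),
    message = dplyr::coalesce(as.character(get("message")), ""),
    date = parse_post_date(get("date")),
    page_name = dplyr::coalesce(as.character(get("page_name", "")), ""),
    page_admin_country = as.character(get("page_admin_country")),
    likes = int_col(get("likes")),
    comments = int_col(get("comments")),
    shares = int_col(get("shares")),
    views = int_col(get("views"))
  )
}

# default CrowdTangle-dialect header spellings, overridable per field
ct_column_map <- function(overrides = NULL) {
  map <- c(
    post_id = "Post ID", message = "Message", date = "Date",
    page_name = "Page Name", page_admin_country = "Page Admin Top Country",
    likes = "Likes", comments = "Comments", shares = "Shares", views = "Views"
  )
  if (!is.null(overrides)) map[names(overrides)] <- overrides
  map
}

parse_post_date <- function(x) {
  x <- as.character(x)
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}([ T].*)?$", x)
  parsed <- as.Date(rep(NA_character_, length(x)))
  parsed[ok] <- as.Date(substr(x[ok], 1, 10))
  bad <- which(is.na(parsed))
  if (length(bad) > 0) {
    ae_abort(paste0("unparseable date in row(s): ",
                    paste(head(bad, 5), collapse = ", "),
                    if (length(bad) > 5) " ..." else ""),
             "aeminer_date_error")
  }
  parsed
}

#' Write a corpus in the CrowdTangle CSV dialect or JSONL mirror
#'
#' @param posts a tibble of posts as returned by [read_corpus()].
#' @param path output path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(posts, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "csv") {
    out <- tibble(
      `Post ID` = posts$post_id, Message = posts$message,
      Date = format(posts$date, "%Y-%m-%d"), `Page Name` = posts$page_name,
      `Page Admin Top Country` = posts$page_admin_country,
      Likes = posts$likes, Comments = posts$comments,
      Shares = posts$shares, Views = posts$views
    )
    readr::write_csv(out, path, progress = FALSE)
  } else {
    rows <- posts
    rows$date <- format(rows$date, "%Y-%m-%d")
    con <- file(path, open = "w")
    on.exit(close(con))
    for (i in seq_len(nrow(rows))) {
      writeLines(jsonlite::toJSON(as.list(rows[i, ]), auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Study inclusion filter
#'
#' Bundles the corpus inclusion criteria: an inclusive calendar date range
#' (day resolution, both endpoints included) and a page-admin country.
#' Defaults are the study window, 2022-01-01 to 2024-05-31, United States
#' pages only.
#'
#' @param start_date,end_date inclusive date range.
#' @param country ISO-3166 alpha-2 page-admin country code.
#' @param drop_empty_messages also drop posts whose message is empty.
#' @return an object of class `corpus_filter`.
#' @export
corpus_filter <- function(start_date = "2022-01-01", end_date = "2024-05-31",
                          country = "US", drop_empty_messages = FALSE) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  stopifnot(!is.na(start_date), !is.na(end_date))
  if (start_date > end_date) {
    ae_abort("start_date must be <= end_date", "aeminer_config_error")
  }
  structure(list(start_date = start_date, end_date = end_date,
                 country = country,
                 drop_empty_messages = isTRUE(drop_empty_messages)),
            class = "corpus_filter")
}

#' Apply date-range and country inclusion filters
#'
#' Filter order is fixed: date range first, then page-admin country.
#' Posts with a missing country (e.g. group posts, which carry no
#' page-admin country) are excluded by the country stage.
#'
#' @param posts a post tibble.
#' @param filter a [corpus_filter()].
#' @return a list with `posts` (the retained rows, input order preserved)
#'   and `report`, a partial filter report with `n_input`, `n_after_date`,
#'   `n_after_country` (the dedup fields are completed by
#'   [filter_corpus()]).
#' @export
apply_filters <- function(posts, filter) {
  stopifnot(inherits(filter, "corpus_filter"))
  n_input <- nrow(posts)
  keep_date <- !is.na(posts$date) &
    posts$date >= filter$start_date & posts$date <= filter$end_date
  if (filter$drop_empty_messages) {
    keep_date <- keep_date & nzchar(posts$message)
  }
  posts <- posts[keep_date, , drop = FALSE]
  n_after_date <- nrow(posts)
  keep_country <- !is.na(posts$page_admin_country) &
    posts$page_admin_country == filter$country
  posts <- posts[keep_country, , drop = FALSE]
  list(posts = posts,
       report = list(n_input = n_input, n_after_date = n_after_date,
                     n_after_country = nrow(posts)))
}

#' Remove exact-duplicate messages
#'
#' One post is retained per distinct message string (byte-exact match, no
#' normalisation: case or whitespace variants are distinct messages). The
#' retained copy is the earliest-dated one, ties broken by input order.
#' Idempotent.
#'
#' @param posts a post tibble.
#' @return a list with `posts` (unique posts, input order preserved) and
#'   `n_removed`.
#' @export
deduplicate <- function(posts) {
  if (nrow(posts) == 0) return(list(posts = posts, n_removed = 0L))
  ord <- order(posts$date, seq_len(nrow(posts)))
  first <- ord[!duplicated(posts$message[ord])]
  keep <- sort(first)
  list(posts = posts[keep, , drop = FALSE],
       n_removed = nrow(posts) - length(keep))
}

#' Run the full inclusion pipeline: date, country, duplicate removal
#'
#' @inheritParams apply_filters
#' @return a list with `posts` and a complete `filter_report` (fields
#'   `n_input`, `n_after_date`, `n_after_country`, `n_after_dedup`,
#'   `n_duplicates_removed`; counts are non-increasing by construction).
#' @export
filter_corpus <- function(posts, filter = corpus_filter()) {
  st <- apply_filters(posts, filter)
  dd <- deduplicate(st$posts)
  report <- c(st$report,
              list(n_after_dedup = nrow(dd$posts),
                   n_duplicates_removed = dd$n_removed))
  stopifnot(report$n_after_country - report$n_after_dedup ==
              report$n_duplicates_removed)
  list(posts = dd$posts, report = structure(report, class = "filter_report"))
}
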