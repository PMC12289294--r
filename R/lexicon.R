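#' The seven adverse-event categories
#' @return character vector of category ids in taxonomy order.
#' @export
ae_categories <- function() {
  c("gastrointestinal", "neuromuscular", "cardiovascular_respiratory",
    "dermatologic_immunologic", "endocrine_metabolic",
    "mental_health_behavioral", "general")
}

#' The seven exclusive drug categories
#'
#' Six specific product categories plus the class-level category, which a
#' post receives only when it mentions the GLP-1 RA class without naming a
#' specific drug.
#' @return character vector of category ids.
#' @export
drug_categories <- function() {
  c("semaglutide", "ozempic", "wegovy", "tirzepatide", "mounjaro",
    "zepbound", "glp1_class")
}

# precedence used to break ties when two specific drugs match at the same
# earliest character position
.drug_precedence <- c("ozempic", "wegovy", "mounjaro", "zepbound",
                      "semaglutide", "tirzepatide")

#' Load the drug and adverse-event lexicons
#'
#' The shipped defaults are two editable CSV files: drug surface forms per
#' category, and 51 adverse-event terms across 7 categories, each with a
#' canonical phrase plus configurable synonym surface forms (the canonical
#' phrase is the first form listed for each term). MD5 checksums of the
#' loaded files are kept for run manifests.
#'
#' @param drug_path,ae_path CSV paths; `NULL` loads the shipped defaults.
#' @return an object of class `ae_lexicon`: list with `drugs`, `aes`
#'   (tibbles of surface forms), and `checksums`.
#' @export
load_lexicon <- function(drug_path = NULL, ae_path = NULL) {
  drug_path <- drug_path %||%
    system.file("extdata", "drug_terms.csv", package = "aeminer")
  ae_path <- ae_path %||%
    system.file("extdata", "ae_terms.csv", package = "aeminer")
  drugs <- readr::read_csv(drug_path, col_types = "cc", progress = FALSE)
  aes <- readr::read_csv(ae_path, col_types = "ccc", progress = FALSE)
  stopifnot(all(c("category_id", "surface_form") %in% names(drugs)),
            all(c("ae_id", "ae_category", "surface_form") %in% names(aes)))
  if (!all(drugs$category_id %in% drug_categories())) {
    ae_abort("unknown drug category in lexicon", "aeminer_lexicon_error")
  }
  if (!all(aes$ae_category %in% ae_categories())) {
    ae_abort("unknown adverse-event category in lexicon",
             "aeminer_lexicon_error")
  }
  if (anyDuplicated(tolower(aes$surface_form))) {
    ae_abort("duplicated adverse-event surface form", "aeminer_lexicon_error")
  }
  structure(
    list(drugs = drugs, aes = aes,
         checksums = c(drug_terms = unname(tools::md5sum(drug_path)),
                       ae_terms = unname(tools::md5sum(ae_path)))),
    class = "ae_lexicon")
}

# one case-insensitive regex matching any of the surface forms, anchored so
# that a hit is not flanked by letters or digits (hyphens inside a form,
# e.g. "GLP-1", are literal); longer forms first so the leftmost hit is the
# longest alternative at that position
term_regex <- function(forms) {
  forms <- forms[order(-nchar(forms))]
  stringr::regex(
    paste0("(?<![\\p{L}\\p{N}])(?:",
           paste(stringr::str_escape(forms), collapse = "|"),
           ")(?![\\p{L}\\p{N}])"),
    ignore_case = TRUE)
}

#' Locate term matches in one message
#'
#' Case-insensitive matching at word boundaries: a hit may not be flanked
#' by a letter or digit on either side. Overlapping hits of the same term
#' (e.g. from nested surface forms) are merged into one span. Offsets are
#' 0-based, half-open.
#'
#' @param message a single message string.
#' @param surface_forms character vector of surface forms for one term.
#' @return tibble with `span_start`, `span_end`, `matched`, ordered by
#'   `span_start`.
#' @export
match_terms <- function(message, surface_forms) {
  stopifnot(length(message) == 1, length(surface_forms) > 0)
  loc <- stringr::str_locate_all(message, term_regex(surface_forms))[[1]]
  if (nrow(loc) == 0) {
    return(tibble(span_start = integer(), span_end = integer(),
                  matched = character()))
  }
  # merge overlapping spans of this term
  loc <- loc[order(loc[, 1], loc[, 2]), , drop = FALSE]
  merged <- list(loc[1, ])
  for (i in seq_len(nrow(loc))[-1]) {
    last <- merged[[length(merged)]]
    if (loc[i, 1] <= last[2]) {
      merged[[length(merged)]] <- c(last[1], max(last[2], loc[i, 2]))
    } else {
      merged[[length(merged) + 1]] <- loc[i, ]
    }
  }
  m <- do.call(rbind, merged)
  tibble(span_start = as.integer(m[, 1] - 1L), span_end = as.integer(m[, 2]),
         matched = substr(rep(message, nrow(m)), m[, 1], m[, 2]))
}

#' Assign each message to exactly one drug category
#'
#' Partition semantics: if any specific-drug surface form matches, the
#' class-level terms are ignored; among several specific drugs, the one
#' whose earliest match starts first wins, ties broken by a fixed
#' precedence (ozempic, wegovy, mounjaro, zepbound, semaglutide,
#' tirzepatide); `glp1_class` only when class terms match and no specific
#' drug does; `NA` when nothing matches.
#'
#' @param messages character vector of messages.
#' @param lexicon an [load_lexicon()] object.
#' @return character vector of category ids (or `NA`), same length as
#'   `messages`.
#' @export
assign_drug_category <- function(messages, lexicon = load_lexicon()) {
  specific <- .drug_precedence
  starts <- matrix(Inf, nrow = length(messages), ncol = length(specific),
                   dimnames = list(NULL, specific))
  for (cat in specific) {
    forms <- lexicon$drugs$surface_form[lexicon$drugs$category_id == cat]
    if (length(forms) == 0) next
    s <- stringr::str_locate(messages, term_regex(forms))[, 1]
    starts[, cat] <- ifelse(is.na(s), Inf, s)
  }
  has_specific <- is.finite(apply(starts, 1, min))
  # earliest start wins; ties resolved by column (precedence) order
  best <- specific[max.col(-starts, ties.method = "first")]
  class_forms <- lexicon$drugs$surface_form[lexicon$drugs$category_id == "glp1_class"]
  has_class <- if (length(class_forms) > 0) {
    stringr::str_detect(messages, term_regex(class_forms))
  } else {
    rep(FALSE, length(messages))
  }
  out <- ifelse(has_specific, best,
                ifelse(has_class, "glp1_class", NA_character_))
  out[is.na(messages)] <- NA_character_
  out
}

#' Extract the set of adverse events mentioned in each message
#'
#' Set semantics: an adverse event counts once per post however many times
#' (or through however many surface forms) it is mentioned. Negation is not
#' handled; any match is a mention.
#'
#' @inheritParams assign_drug_category
#' @return a list of character vectors of canonical `ae_id`s, one per
#'   message (possibly empty).
#' @export
extract_adverse_events <- function(messages, lexicon = load_lexicon()) {
  if (length(messages) == 0) return(list())
  by_ae <- split(lexicon$aes$surface_form, lexicon$aes$ae_id)
  ae_ids <- names(by_ae)
  hits <- vapply(by_ae, function(forms) {
    stringr::str_detect(messages, term_regex(forms))
  }, logical(length(messages)))
  hits <- matrix(hits, nrow = length(messages), ncol = length(ae_ids),
                 dimnames = list(NULL, ae_ids))
  out <- rep(list(character()), length(messages))
  idx <- which(hits, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    found <- split(ae_ids[idx[, 2]], idx[, 1])
    out[as.integer(names(found))] <- lapply(found, sort)
  }
  out
}

#' Annotate a corpus with drug category and adverse-event set
#'
#' Posts that mention no drug category are dropped; every retained post has
#' exactly one category, so category counts partition the annotated corpus.
#'
#' @param posts a (deduplicated) post tibble.
#' @param lexicon an [load_lexicon()] object.
#' @return the post tibble restricted to drug-mentioning posts, with
#'   `drug_category` (character) and `ae_ids` (list of character vectors)
#'   columns added; the lexicon checksums are attached as an attribute.
#' @export
annotate_corpus <- function(posts, lexicon = load_lexicon()) {
  category <- assign_drug_category(posts$message, lexicon)
  keep <- !is.na(category)
  out <- posts[keep, , drop = FALSE]
  out$drug_category <- category[keep]
  out$ae_ids <- extract_adverse_events(out$message, lexicon)
  attr(out, "lexicon_checksums") <- lexicon$checksums
  out
}
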