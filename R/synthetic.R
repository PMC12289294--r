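#' Default drug-category shares
#'
#' Exact post-share fractions of the published 59,293-post partition
#' (e.g. semaglutide 17,146/59,293 = 28.9%).
#'
#' @return named probability vector over the 7 drug categories (sums to 1).
#' @export
default_category_shares <- function() {
  tot <- reference_drug_totals()
  setNames(tot$total_posts / sum(tot$total_posts), tot$category_id)
}

#' Default per-drug adverse-event mention rates
#'
#' Published mention counts divided by per-drug post totals, i.e. the
#' published percentage cells divided by 100 before rounding.
#'
#' @return numeric matrix, 51 adverse events (rows) x 7 drug categories
#'   (columns), entries in `[0, 1]`.
#' @export
default_ae_rates <- function() {
  ref <- reference_ae_counts()
  wide <- tidyr::pivot_wider(ref, id_cols = "ae_id", names_from = "category_id",
                             values_from = "n")
  m <- as.matrix(wide[, drug_categories()])
  rownames(m) <- wide$ae_id
  tot <- reference_drug_totals()
  sweep(m, 2, tot$total_posts[match(colnames(m), tot$category_id)], "/")
}

#' Configuration for the synthetic corpus generator
#'
#' Defaults are the published study conditions: category shares from the
#' exact corpus partition, per-drug adverse-event rates from the published
#' frequency table, the three published co-mention communities as planted
#' clusters, a within-cluster odds boost `rho`, the study date window, and
#' a duplicate share equal to the one implied by the published corpus sizes
#' (64,202 collected, 59,293 after duplicate removal).
#'
#' @param n_posts number of posts to generate.
#' @param start_date,end_date post date range (uniform over days).
#' @param category_shares named probability vector over the 7 drug
#'   categories; must sum to 1 (tolerance 1e-9).
#' @param ae_rates adverse-event x drug-category matrix of per-post mention
#'   probabilities.
#' @param clusters named list of disjoint `ae_id` sets; membership of an
#'   active cluster boosts co-mention odds.
#' @param rho within-cluster co-mention odds boost factor, `>= 1`
#'   (`rho = 1` means adverse-event indicators are independent).
#' @param duplicate_rate probability that a post clones an earlier message.
#' @param offfilter_rate probability that a post violates exactly one
#'   inclusion criterion (page-admin country or date range).
#' @param seed integer RNG seed; generation is deterministic given the
#'   config.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_posts,
                             start_date = "2022-01-01",
                             end_date = "2024-05-31",
                             category_shares = default_category_shares(),
                             ae_rates = default_ae_rates(),
                             clusters = default_clusters(),
                             rho = 8,
                             duplicate_rate = 4909 / 64202,
                             offfilter_rate = 0,
                             seed = 0) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date) || start_date > end_date) {
    ae_abort("invalid date range", "aeminer_config_error")
  }
  if (!setequal(names(category_shares), drug_categories())) {
    ae_abort("category_shares must name the 7 drug categories",
             "aeminer_config_error")
  }
  if (any(category_shares < 0) || abs(sum(category_shares) - 1) > 1e-9) {
    ae_abort("category_shares must be a probability vector summing to 1",
             "aeminer_config_error")
  }
  if (any(ae_rates < 0 | ae_rates > 1) || is.null(rownames(ae_rates))) {
    ae_abort("ae_rates must be probabilities with ae_id rownames",
             "aeminer_config_error")
  }
  if (!all(colnames(ae_rates) %in% drug_categories())) {
    ae_abort("ae_rates columns must be drug categories", "aeminer_config_error")
  }
  members <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(members)) {
    ae_abort("clusters must be disjoint", "aeminer_config_error")
  }
  if (!all(members %in% rownames(ae_rates))) {
    ae_abort("cluster members must be known adverse events",
             "aeminer_config_error")
  }
  if (rho < 1) ae_abort("rho must be >= 1", "aeminer_config_error")
  if (duplicate_rate < 0 || duplicate_rate >= 1 ||
      offfilter_rate < 0 || offfilter_rate >= 1) {
    ae_abort("duplicate_rate and offfilter_rate must be in [0, 1)",
             "aeminer_config_error")
  }
  structure(list(n_posts = as.integer(n_posts), start_date = start_date,
                 end_date = end_date,
                 category_shares = category_shares[drug_categories()],
                 ae_rates = ae_rates, clusters = clusters, rho = rho,
                 duplicate_rate = duplicate_rate,
                 offfilter_rate = offfilter_rate, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic corpus with a ground-truth ledger
#'
#' Each post draws a drug category from the configured shares and carries a
#' neutral template sentence embedding that category's canonical surface
#' form. Adverse events are included independently at their per-category
#' rates; then, for each configured cluster with at least one member drawn,
#' the remaining members' inclusion odds are multiplied by `rho`
#' (odds-scaling keeps probabilities below 1), planting excess co-mention
#' within clusters while leaving between-cluster pairs independent. Dates
#' are uniform over the range. With probability `duplicate_rate` a post
#' clones an earlier message (its date drawn at or after the source's, so
#' earliest-copy dedup retains the original); with probability
#' `offfilter_rate` a post violates exactly one inclusion criterion
#' (country or date). Non-duplicate messages carry a unique serial token so
#' that exact-message identity coincides with the ledger's duplicate flags.
#'
#' @param config a [generator_config()].
#' @param lexicon lexicon supplying canonical surface forms.
#' @return list with `posts` (CrowdTangle-dialect tibble) and `ledger`
#'   (per-post true category, true adverse-event set, duplicate and
#'   off-filter flags; realized counts attached as attribute `realized`).
#' @export
generate_corpus <- function(config, lexicon = load_lexicon()) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_corpus_impl(config, lexicon))
}

generate_corpus_impl <- function(config, lexicon) {
  n <- config$n_posts
  rates <- config$ae_rates
  ae_ids <- rownames(rates)
  category <- sample(names(config$category_shares), n, replace = TRUE,
                     prob = config$category_shares)

  # base independent draws at the per-category rates
  p_mat <- t(rates[, category, drop = FALSE])        # n x n_ae
  base <- matrix(runif(n * length(ae_ids)), nrow = n) < p_mat
  incl <- base

  # within-cluster odds boost, triggered by the independent base draws
  for (cl in config$clusters) {
    j_idx <- match(cl, ae_ids)
    active <- rowSums(base[, j_idx, drop = FALSE]) > 0
    for (j in j_idx) {
      p <- p_mat[, j]
      p_boost <- config$rho * p / (1 - p + config$rho * p)
      second <- ifelse(p < 1, (p_boost - p) / (1 - p), 0)
      cand <- which(active & !base[, j])
      if (length(cand) > 0) {
        incl[cand, j] <- runif(length(cand)) < second[cand]
      }
    }
  }

  ae_sets <- apply(incl, 1, function(r) ae_ids[r], simplify = FALSE)

  # neutral carrier sentences; serial token keeps originals distinct
  drug_canon <- vapply(split(lexicon$drugs$surface_form,
                             lexicon$drugs$category_id), `[`, character(1), 1)
  ae_canon <- vapply(split(lexicon$aes$surface_form, lexicon$aes$ae_id),
                     `[`, character(1), 1)
  ae_phrase <- vapply(ae_sets, function(s) {
    paste(ae_canon[s], collapse = " and ")
  }, character(1))
  tmpl <- sample.int(3, n, replace = TRUE)
  drug_word <- drug_canon[category]
  serial <- seq_len(n)
  message <- character(n)
  has_ae <- lengths(ae_sets) > 0
  with_ae <- c("Been on %s for a few weeks and dealing with %s. (entry %d)",
               "My experience with %s so far: %s. (entry %d)",
               "Started %s recently; since then %s. (entry %d)")
  without_ae <- c("Been on %s for a few weeks and feeling fine. (entry %d)",
                  "My experience with %s so far: no complaints. (entry %d)",
                  "Started %s recently; so far so good. (entry %d)")
  message[has_ae] <- sprintf(with_ae[tmpl[has_ae]], drug_word[has_ae],
                             ae_phrase[has_ae], serial[has_ae])
  message[!has_ae] <- sprintf(without_ae[tmpl[!has_ae]], drug_word[!has_ae],
                              serial[!has_ae])

  n_days <- as.integer(config$end_date - config$start_date) + 1L
  date <- config$start_date + (sample.int(n_days, n, replace = TRUE) - 1L)
  country <- rep("US", n)

  is_dup <- runif(n) < config$duplicate_rate
  is_dup[1] <- FALSE
  is_off <- !is_dup & runif(n) < config$offfilter_rate
  off_mode <- rep("none", n)
  off_idx <- which(is_off)
  if (length(off_idx) > 0) {
    off_mode[off_idx] <- sample(c("country", "date"), length(off_idx),
                                replace = TRUE)
    for (i in off_idx) {
      if (off_mode[i] == "country") {
        country[i] <- sample(c("GB", "CA", "AU"), 1)
      } else {
        if (runif(1) < 0.5) {
          date[i] <- config$start_date - sample.int(120, 1)
        } else {
          date[i] <- config$end_date + sample.int(120, 1)
        }
      }
    }
  }

  # clones copy message and truth from a surviving (non-off-filter) source
  dup_of <- rep(NA_integer_, n)
  for (i in which(is_dup)) {
    pool <- which(!is_off[seq_len(i - 1)])
    if (length(pool) == 0) {
      is_dup[i] <- FALSE
      next
    }
    src <- pool[sample.int(length(pool), 1)]
    dup_of[i] <- src
    message[i] <- message[src]
    category[i] <- category[src]
    ae_sets[[i]] <- ae_sets[[src]]
    slack <- as.integer(config$end_date - date[src])
    date[i] <- date[src] + (sample.int(slack + 1L, 1) - 1L)
  }

  post_id <- sprintf("p%06d", seq_len(n))
  posts <- tibble(
    post_id = post_id, message = message, date = date,
    page_name = paste0("Wellness Community ", sample.int(25, n, replace = TRUE)),
    page_admin_country = country,
    likes = rpois(n, 20), comments = rpois(n, 5), shares = rpois(n, 3),
    views = rpois(n, 400)
  )
  ledger <- tibble(
    post_id = post_id, true_category = unname(category),
    true_aes = vapply(ae_sets, paste, character(1), collapse = ";"),
    n_true_aes = lengths(ae_sets),
    is_duplicate = is_dup,
    duplicate_of = ifelse(is.na(dup_of), NA_character_, post_id[dup_of]),
    off_filter = off_mode
  )
  attr(ledger, "realized") <- list(
    n_posts = n,
    category_counts = table(category),
    n_duplicates = sum(is_dup),
    n_off_filter = sum(is_off)
  )
  list(posts = posts, ledger = ledger)
}

#' Configuration for a planted-cluster co-occurrence experiment
#'
#' All cluster-member adverse events get the same base mention rate (other
#' adverse events are silent), so expected co-occurrence counts are
#' analytically tractable: between-cluster pairs co-occur at the
#' independent rate while within-cluster pairs are inflated by the odds
#' boost (see [planted_pair_expectation()]).
#'
#' @param clusters named list of disjoint `ae_id` sets to plant.
#' @param base_rate per-post base mention probability for member events.
#' @param rho within-cluster odds boost, `>= 1`.
#' @param n_posts,seed passed to [generator_config()].
#' @return a [generator_config()] with no duplicates or off-filter noise.
#' @export
planted_network_config <- function(clusters = default_clusters(),
                                   base_rate = 0.05, rho = 8,
                                   n_posts = 20000, seed = 0) {
  all_ids <- sort(unique(reference_ae_counts()$ae_id))
  rates <- matrix(0, nrow = length(all_ids), ncol = length(drug_categories()),
                  dimnames = list(all_ids, drug_categories()))
  members <- unlist(clusters, use.names = FALSE)
  rates[members, ] <- base_rate
  generator_config(n_posts = n_posts, category_shares = default_category_shares(),
                   ae_rates = rates, clusters = clusters, rho = rho,
                   duplicate_rate = 0, offfilter_rate = 0, seed = seed)
}

#' Approximate per-post pair-mention probabilities under the planted model
#'
#' Two-member approximation ignoring boosts mediated by further cluster
#' members: a within-cluster pair co-occurs with probability
#' `p^2 + 2 p (p_boost - p)` where `p_boost` is the odds-boosted rate,
#' while a between-cluster pair co-occurs at the independent `p^2`. At
#' `rho = 1` the two coincide (ratio 1, no signal).
#'
#' @param base_rate per-post base mention probability.
#' @param rho odds boost factor.
#' @return list with `within`, `between`, and their `ratio`.
#' @export
planted_pair_expectation <- function(base_rate, rho) {
  p <- base_rate
  p_boost <- rho * p / (1 - p + rho * p)
  within <- p^2 + 2 * p * (p_boost - p)
  list(within = within, between = p^2, ratio = within / p^2)
}

#' Expected share of posts mentioning any adverse event
#'
#' Closed form under independence (`rho = 1`): the share-weighted
#' complement `sum_c share_c (1 - prod_a (1 - p_{a,c}))`, in percent.
#'
#' @param config a [generator_config()].
#' @return expected percentage of posts with a non-empty adverse-event set.
#' @export
expected_ae_share <- function(config) {
  shares <- config$category_shares
  p_none <- apply(1 - config$ae_rates[, names(shares), drop = FALSE], 2, prod)
  100 * sum(shares * (1 - p_none))
}
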