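# small corpus builder in the canonical post schema
make_posts <- function(message,
                       date = rep("2023-06-15", length(message)),
                       country = rep("US", length(message)),
                       page_name = "Test Page") {
  tibble::tibble(
    post_id = sprintf("t%03d", seq_along(message)),
    message = message,
    date = as.Date(date),
    page_name = page_name,
    page_admin_country = country,
    likes = 0L, comments = 0L, shares = 0L, views = 0L
  )
}

# random weighted undirected graph on n nodes (at least one edge)
rand_weighted_graph <- function(n, p = 0.5, wmax = 5) {
  repeat {
    ne <- n * (n - 1) / 2
    am <- matrix(0, n, n)
    am[upper.tri(am)] <- (runif(ne) < p) * sample(seq_len(wmax), ne, TRUE)
    if (sum(am) > 0) break
  }
  idx <- which(am > 0, arr.ind = TRUE)
  cooccurrence_graph(letters[idx[, 1]], letters[idx[, 2]], am[idx])
}

# planted-cluster truth labels, named by ae_id
planted_truth <- function(clusters = default_clusters()) {
  unlist(lapply(names(clusters), function(cl) {
    stats::setNames(rep(cl, length(clusters[[cl]])), clusters[[cl]])
  }))
}

# independent oracle: count co-mention pairs by scanning every post
brute_force_pair_counts <- function(ae_sets) {
  counts <- list()
  for (s in ae_sets) {
    s <- sort(s)
    if (length(s) < 2) next
    for (i in seq_len(length(s) - 1)) {
      for (j in (i + 1):length(s)) {
        key <- paste(s[i], s[j], sep = "|")
        counts[[key]] <- (counts[[key]] %||% 0) + 1
      }
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
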