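#' Seeded Fruchterman-Reingold spring layout
#'
#' Force-directed placement with optimal-distance constant `k`: every node
#' pair repels with force `k^2 / d`, every edge attracts with force
#' `d^2 / k` scaled by its weight relative to the maximum weight.
#' Displacements are capped by a temperature that cools linearly over the
#' iterations. Initial positions are drawn uniformly in the unit square
#' under `seed` (or supplied explicitly), so coordinates are
#' bit-reproducible.
#'
#' @param graph a non-empty `cooccurrence_graph`.
#' @param k optimal-distance constant (default 7.8).
#' @param iterations number of cooling steps (default 100).
#' @param seed integer seed for the initial placement.
#' @param initial optional n x 2 matrix of starting coordinates
#'   (row order = node order), overriding the seeded draw.
#' @return tibble with `ae_id`, `x`, `y`.
#' @export
spring_layout <- function(graph, k = 7.8, iterations = 100, seed = 0,
                          initial = NULL) {
  ids <- graph$nodes$ae_id
  n <- length(ids)
  if (n == 0) ae_abort("layout needs at least one node", "aeminer_graph_error")
  if (n == 1) return(tibble(ae_id = ids, x = 0, y = 0))
  pos <- if (is.null(initial)) {
    withr::with_seed(seed, matrix(runif(2 * n), ncol = 2))
  } else {
    stopifnot(nrow(initial) == n, ncol(initial) == 2)
    initial
  }
  ei <- match(graph$edges$from, ids)
  ej <- match(graph$edges$to, ids)
  w <- if (nrow(graph$edges) > 0) {
    graph$edges$weight / max(graph$edges$weight)
  } else {
    numeric(0)
  }
  t0 <- 0.1
  dt <- t0 / (iterations + 1)
  temp <- t0
  for (step in seq_len(iterations)) {
    dx <- outer(pos[, 1], pos[, 1], "-")
    dy <- outer(pos[, 2], pos[, 2], "-")
    d <- sqrt(dx^2 + dy^2)
    d[d < 0.01] <- 0.01
    # repulsion between all pairs
    rep_f <- k^2 / d
    diag(rep_f) <- 0
    disp_x <- rowSums(dx / d * rep_f)
    disp_y <- rowSums(dy / d * rep_f)
    # attraction along edges, weight-scaled
    if (length(ei) > 0) {
      ax <- pos[ei, 1] - pos[ej, 1]
      ay <- pos[ei, 2] - pos[ej, 2]
      ad <- pmax(sqrt(ax^2 + ay^2), 0.01)
      f <- ad^2 / k * w
      fx <- ax / ad * f
      fy <- ay / ad * f
      disp_x <- disp_x - tabulate2(ei, fx, n) + tabulate2(ej, fx, n)
      disp_y <- disp_y - tabulate2(ei, fy, n) + tabulate2(ej, fy, n)
    }
    len <- pmax(sqrt(disp_x^2 + disp_y^2), 1e-12)
    scale <- pmin(len, temp) / len
    pos[, 1] <- pos[, 1] + disp_x * scale
    pos[, 2] <- pos[, 2] + disp_y * scale
    temp <- temp - dt
  }
  tibble(ae_id = ids, x = pos[, 1], y = pos[, 2])
}

# sum values into bins (deterministic order)
tabulate2 <- function(index, values, n) {
  out <- numeric(n)
  for (i in seq_along(index)) out[index[i]] <- out[index[i]] + values[i]
  out
}
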