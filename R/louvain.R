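#' Louvain community detection by weighted modularity optimisation
#'
#' From-scratch two-phase Louvain: repeated local node moves that maximise
#' the modularity gain
#' `dQ = k_i,in / m - gamma * Sigma_tot * k_i / (2 m^2)` (evaluated with
#' the node removed from its community), followed by aggregation of each
#' community into a super-node (internal weight becoming a self-loop), and
#' iterated until a full level yields modularity gain below `tol`. Node
#' visit order is shuffled once per sweep under `seed`, so results are
#' bit-reproducible for a fixed seed.
#'
#' Because the local phase is greedy, a single visit order can stall in a
#' local optimum; the optimiser therefore runs `restarts` independent
#' passes with freshly shuffled orders (all derived from `seed`) and keeps
#' the partition with the highest modularity. On small graphs this
#' reliably reaches the exhaustive-search optimum.
#'
#' @param graph a `cooccurrence_graph` with at least one edge.
#' @param seed integer seed controlling node visit order.
#' @param resolution resolution parameter `gamma` (1 = standard
#'   modularity).
#' @param tol minimum modularity gain to accept another level.
#' @param max_passes cap on outer levels.
#' @param restarts independent restarts; the best-modularity partition
#'   wins (ties to the earliest restart).
#' @return an object of class `community_partition`: list with
#'   `membership` (named integer vector over the original nodes, labels
#'   `1..K` in order of first appearance), `modularity` (`Q`, recomputed
#'   from the partition), and `q_trace` (`Q` after each level;
#'   non-decreasing).
#' @export
louvain <- function(graph, seed = 0, resolution = 1, tol = 1e-7,
                    max_passes = 100, restarts = 10) {
  if (nrow(graph$edges) == 0) {
    ae_abort("community detection needs at least one edge",
             "aeminer_graph_error")
  }
  withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      cand <- louvain_impl(graph, resolution, tol, max_passes)
      if (is.null(best) || cand$modularity > best$modularity + 1e-12) {
        best <- cand
      }
    }
    best
  })
}

louvain_impl <- function(graph, resolution, tol, max_passes) {
  ids <- graph$nodes$ae_id
  A <- graph_adjacency(graph)       # zero diagonal at level 0
  membership <- seq_along(ids)      # projection of current level onto nodes
  q_trace <- numeric(0)
  q_prev <- graph_modularity(graph, setNames(membership, ids), resolution)

  for (pass in seq_len(max_passes)) {
    comm <- louvain_one_level(A, resolution)
    comm <- match(comm, unique(comm))           # compact labels 1..K
    membership <- comm[membership]
    q_now <- graph_modularity(graph, setNames(membership, ids), resolution)
    q_trace <- c(q_trace, q_now)
    n_comm <- max(comm)
    if (n_comm == nrow(A) || q_now - q_prev < tol) break
    q_prev <- q_now
    # aggregate communities into super-nodes; internal weight -> diagonal
    S <- matrix(0, nrow(A), n_comm)
    S[cbind(seq_len(nrow(A)), comm)] <- 1
    A <- t(S) %*% A %*% S
  }

  membership <- match(membership, unique(membership))
  part <- structure(
    list(membership = setNames(as.integer(membership), ids),
         modularity = graph_modularity(graph, setNames(membership, ids),
                                       resolution),
         q_trace = q_trace),
    class = "community_partition")
  part
}

# one sweep phase of local moves on adjacency A (diagonal = self-loops,
# counted twice in degrees); returns the community label per node
louvain_one_level <- function(A, resolution) {
  n <- nrow(A)
  comm <- seq_len(n)
  k <- rowSums(A)
  two_m <- sum(A)
  s_tot <- k
  repeat {
    n_moved <- 0L
    for (i in sample.int(n)) {
      ci <- comm[i]
      nb <- which(A[i, ] > 0)
      nb <- nb[nb != i]
      if (length(nb) == 0) next
      w_ic <- tapply(A[i, nb], comm[nb], sum)
      s_tot[ci] <- s_tot[ci] - k[i]
      cand <- as.integer(names(w_ic))
      if (!(ci %in% cand)) {
        cand <- c(cand, ci)
        w_ic <- c(w_ic, setNames(0, ci))
      }
      gain <- w_ic[as.character(cand)] -
        resolution * s_tot[cand] * k[i] / two_m
      best_gain <- max(gain)
      winners <- cand[gain >= best_gain - 1e-12]
      target <- if (ci %in% winners) ci else min(winners)
      s_tot[target] <- s_tot[target] + k[i]
      if (target != ci) {
        comm[i] <- target
        n_moved <- n_moved + 1L
      }
    }
    if (n_moved == 0L) break
  }
  comm
}

#' Exact modularity-optimal partition by exhaustive enumeration
#'
#' Enumerates every set partition (restricted-growth-string order) of the
#' node set and returns the first partition attaining the maximum
#' modularity, i.e. ties break to the lexicographically smallest canonical
#' labelling. A test oracle: refuses graphs with more than 10 nodes
#' (Bell(10) = 115,975 partitions).
#'
#' @param graph a `cooccurrence_graph` with at most 10 nodes.
#' @param resolution resolution parameter.
#' @return a `community_partition` (as in [louvain()], without `q_trace`).
#' @export
brute_force_best_partition <- function(graph, resolution = 1) {
  n <- nrow(graph$nodes)
  if (n > 10) {
    ae_abort("exhaustive search is limited to graphs with <= 10 nodes",
             "aeminer_graph_error")
  }
  if (nrow(graph$edges) == 0) {
    ae_abort("modularity is undefined on a graph with no edges",
             "aeminer_graph_error")
  }
  A <- graph_adjacency(graph)
  k <- rowSums(A)
  two_m <- sum(A)
  best_q <- -Inf
  best <- NULL
  # enumerate restricted growth strings a (a[1] = 1, a[j] <= b[j] where
  # b[j] = 1 + max(a[1:(j-1)])) in lexicographic order
  a <- rep(1L, n)
  b <- c(1L, rep(2L, n - 1))
  repeat {
    same <- outer(a, a, "==")
    q <- sum(A[same]) / two_m -
      resolution * sum(tapply(k, a, sum)^2) / two_m^2
    if (q > best_q + 1e-15) {
      best_q <- q
      best <- a
    }
    i <- n
    while (i > 1 && a[i] >= b[i]) i <- i - 1
    if (i == 1) break
    a[i] <- a[i] + 1L
    if (i < n) {
      for (j in (i + 1):n) {
        a[j] <- 1L
        b[j] <- max(b[j - 1], a[j - 1] + 1L)
      }
    }
  }
  structure(
    list(membership = setNames(as.integer(best), graph$nodes$ae_id),
         modularity = best_q),
    class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("Community partition:", length(unique(x$membership)), "communities,",
      "Q =", format(x$modularity, digits = 6), "\n")
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to relabeling), about 0 for independent
#' ones.
#'
#' @param a,b label vectors of equal length (names ignored; positions must
#'   correspond).
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
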