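#' Build the weighted adverse-event co-occurrence graph
#'
#' Nodes are adverse events, node frequency is the number of distinct posts
#' mentioning the event, and the weight of edge (i, j) is the number of
#' posts mentioning both. Undirected, no self-loops; adverse events that
#' never co-occur (weight below `min_weight` on every pair) are excluded
#' from the graph.
#'
#' @param annotated an annotated corpus.
#' @param min_weight minimum edge weight to retain (default 1: every
#'   co-occurring pair).
#' @return an object of class `cooccurrence_graph`: list with `nodes`
#'   (`ae_id`, `frequency`) and `edges` (`from`, `to`, `weight`, with
#'   `from < to`).
#' @export
build_cooccurrence <- function(annotated, min_weight = 1) {
  ae_ids <- sort(unique(unlist(annotated$ae_ids, use.names = FALSE)))
  if (length(ae_ids) == 0) {
    return(new_cooccurrence_graph(
      tibble(ae_id = character(), frequency = integer()),
      tibble(from = character(), to = character(), weight = integer())))
  }
  inc <- matrix(FALSE, nrow = nrow(annotated), ncol = length(ae_ids),
                dimnames = list(NULL, ae_ids))
  rows <- rep(seq_len(nrow(annotated)), lengths(annotated$ae_ids))
  cols <- match(unlist(annotated$ae_ids, use.names = FALSE), ae_ids)
  inc[cbind(rows, cols)] <- TRUE
  co <- crossprod(inc)
  ut <- which(upper.tri(co) & co >= max(1, min_weight), arr.ind = TRUE)
  edges <- tibble(from = ae_ids[ut[, 1]], to = ae_ids[ut[, 2]],
                  weight = as.integer(co[ut]))
  keep <- sort(unique(c(edges$from, edges$to)))
  nodes <- tibble(ae_id = keep,
                  frequency = as.integer(colSums(inc)[keep]))
  new_cooccurrence_graph(nodes, edges)
}

new_cooccurrence_graph <- function(nodes, edges) {
  stopifnot(all(edges$from != edges$to), all(edges$weight >= 1) || nrow(edges) == 0)
  structure(list(nodes = nodes, edges = edges), class = "cooccurrence_graph")
}

#' Construct a co-occurrence graph from an explicit edge list
#'
#' Mostly for tests and small worked examples.
#'
#' @param from,to node name vectors.
#' @param weight positive edge weights (default 1).
#' @return a `cooccurrence_graph`.
#' @export
cooccurrence_graph <- function(from, to, weight = 1) {
  weight <- rep_len(weight, length(from))
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  nodes <- sort(unique(c(from, to)))
  edges <- tibble(from = from, to = to, weight = weight) |>
    group_by(.data$from, .data$to) |>
    summarise(weight = sum(.data$weight), .groups = "drop")
  new_cooccurrence_graph(
    tibble(ae_id = nodes, frequency = NA_integer_), edges)
}

#' @export
print.cooccurrence_graph <- function(x, ...) {
  cat("Co-occurrence graph:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges, total weight", sum(x$edges$weight), "\n")
  invisible(x)
}

# dense symmetric adjacency matrix (zero diagonal) in node order
graph_adjacency <- function(graph) {
  ids <- graph$nodes$ae_id
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  i <- match(graph$edges$from, ids)
  j <- match(graph$edges$to, ids)
  A[cbind(i, j)] <- graph$edges$weight
  A[cbind(j, i)] <- graph$edges$weight
  A
}

#' Weighted modularity of a partition
#'
#' Newman-Girvan modularity on the weighted graph,
#' `Q = sum_c [ S_in,c / (2m) - (S_tot,c / (2m))^2 ]`, where `m` is the
#' total edge weight, `S_in,c` twice the internal weight of community `c`
#' and `S_tot,c` the summed weighted degrees, at resolution
#' `gamma` (default 1).
#'
#' @param graph a `cooccurrence_graph`.
#' @param membership named vector (by node id) of community labels
#'   covering every node.
#' @param resolution resolution parameter `gamma`.
#' @return modularity `Q` in `[-0.5, 1]`.
#' @export
graph_modularity <- function(graph, membership, resolution = 1) {
  if (nrow(graph$edges) == 0) {
    ae_abort("modularity is undefined on a graph with no edges",
             "aeminer_graph_error")
  }
  ids <- graph$nodes$ae_id
  if (!all(ids %in% names(membership))) {
    ae_abort("membership must cover every graph node", "aeminer_graph_error")
  }
  comm <- as.character(membership[ids])
  A <- graph_adjacency(graph)
  two_m <- sum(A)
  k <- rowSums(A)
  s_in <- tapply(rowSums(A * outer(comm, comm, "==")), comm, sum)
  s_tot <- tapply(k, comm, sum)
  sum(s_in / two_m - resolution * (s_tot / two_m)^2)
}

#' Assign edges to the published width tiers
#'
#' Thick for co-occurrence counts of at least 100, moderate for counts in
#' `[50, 100)`, thin below 50 (the published "between 50 and 100" band is
#' resolved half-open at 100).
#'
#' @param graph a `cooccurrence_graph`.
#' @return the edge tibble with a `tier` factor
#'   (`thin < moderate < thick`).
#' @export
tier_edges <- function(graph) {
  w <- graph$edges$weight
  tier <- cut(w, breaks = c(-Inf, 50, 100, Inf),
              labels = c("thin", "moderate", "thick"), right = FALSE)
  dplyr::mutate(graph$edges, tier = tier)
}

#' Convert to an igraph object
#'
#' Node frequency, community and edge weight/tier travel as attributes;
#' used for GraphML export and for cross-checks against igraph's own
#' implementations.
#'
#' @param graph a `cooccurrence_graph`.
#' @param membership optional named community labels.
#' @return an igraph graph.
#' @export
as_igraph <- function(graph, membership = NULL) {
  tiers <- tier_edges(graph)
  vert <- graph$nodes
  vert$name <- vert$ae_id
  if (!is.null(membership)) {
    vert$community <- as.character(membership[vert$ae_id])
  }
  igraph::graph_from_data_frame(
    d = data.frame(from = tiers$from, to = tiers$to,
                   weight = tiers$weight, tier = as.character(tiers$tier)),
    directed = FALSE,
    vertices = vert[, c("name", setdiff(names(vert), c("name", "ae_id")))])
}

#' Export a graph as GraphML
#'
#' @inheritParams as_igraph
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path, membership = NULL) {
  igraph::write_graph(as_igraph(graph, membership), path, format = "graphml")
  invisible(path)
}

#' Export the edge list as TSV
#'
#' @param graph a `cooccurrence_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  readr::write_tsv(tier_edges(graph), path, progress = FALSE)
  invisible(path)
}
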