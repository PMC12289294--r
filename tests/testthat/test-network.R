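lex <- load_lexicon()

test_that("co-occurrence weights count posts mentioning both endpoints", {
  posts <- make_posts(c("ozempic nausea vomiting and gi issues",
                        "wegovy nausea", "mounjaro fatigue"))
  ann <- annotate_corpus(posts, lex)
  gr <- build_cooccurrence(ann)
  # one triple-mention post yields a unit-weight triangle; the singleton
  # mentions contribute no edges and their nodes are excluded
  expect_setequal(gr$nodes$ae_id,
                  c("gastrointestinal_general", "nausea", "vomiting"))
  expect_equal(nrow(gr$edges), 3)
  expect_true(all(gr$edges$weight == 1))
  # node frequency counts distinct mentioning posts corpus-wide
  expect_equal(gr$nodes$frequency[gr$nodes$ae_id == "nausea"], 2L)

  # singleton-only corpus: empty edge set
  solo <- annotate_corpus(make_posts(c("ozempic nausea", "wegovy fatigue")),
                          lex)
  expect_equal(nrow(build_cooccurrence(solo)$edges), 0)
})

test_that("co-occurrence matches a brute-force pair scan on a synthetic corpus", {
  gen <- generate_corpus(generator_config(n_posts = 500, duplicate_rate = 0,
                                          seed = 17))
  ann <- annotate_corpus(gen$posts, lex)
  gr <- build_cooccurrence(ann)
  oracle <- brute_force_pair_counts(ann$ae_ids)
  expect_equal(nrow(gr$edges), length(oracle))
  for (i in seq_len(nrow(gr$edges))) {
    key <- paste(gr$edges$from[i], gr$edges$to[i], sep = "|")
    expect_equal(gr$edges$weight[i], oracle[[key]])
  }
  # total edge weight equals the sum over posts of choose(|S|, 2)
  expect_equal(sum(gr$edges$weight),
               sum(choose(lengths(ann$ae_ids), 2)))
})

test_that("modularity matches closed forms and the reference implementation", {
  tri2 <- cooccurrence_graph(c("a", "a", "b", "x", "x", "y"),
                             c("b", "c", "c", "y", "z", "z"))
  by_comp <- setNames(c(1, 1, 1, 2, 2, 2), c("a", "b", "c", "x", "y", "z"))
  expect_equal(graph_modularity(tri2, by_comp), 0.5)
  # the all-in-one community always scores zero
  expect_equal(graph_modularity(tri2, setNames(rep(1, 6), names(by_comp))), 0)

  withr::with_seed(88, {
    for (i in 1:10) {
      gr <- rand_weighted_graph(8)
      memb <- setNames(sample(1:3, nrow(gr$nodes), TRUE), gr$nodes$ae_id)
      ig <- as_igraph(gr)
      q_ref <- igraph::modularity(ig, memb[igraph::V(ig)$name],
                                  weights = igraph::E(ig)$weight)
      expect_equal(graph_modularity(gr, memb), q_ref, tolerance = 1e-9)
    }
  })

  # single all-inclusive community is zero on random graphs too
  withr::with_seed(89, {
    gr <- rand_weighted_graph(7)
    memb <- setNames(rep(1, nrow(gr$nodes)), gr$nodes$ae_id)
    expect_equal(graph_modularity(gr, memb), 0)
  })

  expect_error(graph_modularity(tri2, by_comp[1:3]),
               class = "aeminer_graph_error")
  empty <- cooccurrence_graph(character(), character(), numeric())
  expect_error(graph_modularity(empty, setNames(integer(), character())),
               class = "aeminer_graph_error")
})

test_that("exhaustive search matches hand enumeration on tiny graphs", {
  # two disjoint unit edges: split by component, Q = 0.5
  two_edges <- cooccurrence_graph(c("a", "c"), c("b", "d"))
  bf <- brute_force_best_partition(two_edges)
  expect_equal(bf$modularity, 0.5)
  expect_equal(unname(bf$membership[c("a", "b")]),
               rep(bf$membership[["a"]], 2))
  expect_false(bf$membership[["a"]] == bf$membership[["c"]])

  # single edge: one community, Q = 0 (two singletons would give -0.5)
  one_edge <- cooccurrence_graph("a", "b")
  bf1 <- brute_force_best_partition(one_edge)
  expect_equal(bf1$modularity, 0)
  expect_equal(length(unique(bf1$membership)), 1)

  # path a-b-c: of the 5 partitions, the single community is optimal
  # (hand enumeration: {abc} 0, {ab}{c} -0.125, {a}{bc} -0.125,
  #  {ac}{b} -0.5, singletons -0.375)
  path3 <- cooccurrence_graph(c("a", "b"), c("b", "c"))
  bf3 <- brute_force_best_partition(path3)
  expect_equal(bf3$modularity, 0)
  expect_equal(length(unique(bf3$membership)), 1)

  big <- cooccurrence_graph(letters[1:11], c(letters[2:11], "a"))
  expect_error(brute_force_best_partition(big), class = "aeminer_graph_error")
})

test_that("louvain recovers exact structure on canonical graphs", {
  tri2 <- cooccurrence_graph(c("a", "a", "b", "x", "x", "y"),
                             c("b", "c", "c", "y", "z", "z"))
  part <- louvain(tri2, seed = 1)
  expect_equal(part$modularity, 0.5)
  expect_equal(length(unique(part$membership)), 2)
  expect_equal(length(unique(part$membership[c("a", "b", "c")])), 1)

  # complete graph: any split lowers Q, so one community
  k5 <- with(expand.grid(i = 1:5, j = 1:5), {
    keep <- i < j
    cooccurrence_graph(letters[i[keep]], letters[j[keep]])
  })
  expect_equal(length(unique(louvain(k5, seed = 1)$membership)), 1)
})

test_that("louvain is seeded, monotone, and beats the singleton partition", {
  withr::with_seed(99, gr <- rand_weighted_graph(8))
  p1 <- louvain(gr, seed = 5)
  p2 <- louvain(gr, seed = 5)
  expect_identical(p1, p2)
  expect_true(all(diff(p1$q_trace) >= -1e-12))
  singletons <- setNames(seq_len(nrow(gr$nodes)), gr$nodes$ae_id)
  expect_gte(p1$modularity, graph_modularity(gr, singletons))
  # reported Q is self-consistent with the returned partition
  expect_equal(p1$modularity, graph_modularity(gr, p1$membership),
               tolerance = 1e-12)
})

test_that("louvain attains the exhaustive optimum on small random graphs", {
  withr::with_seed(77, {
    for (r in 1:10) {
      gr <- rand_weighted_graph(sample(4:7, 1))
      bf <- brute_force_best_partition(gr)
      lv <- louvain(gr, seed = r)
      expect_lt(abs(bf$modularity - lv$modularity), 1e-6)
    }
  })
})

test_that("adjusted Rand index matches the mclust reference", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 1), c(1, 1, 1)), 1)
  withr::with_seed(12, {
    for (i in 1:10) {
      a <- sample(1:4, 40, TRUE)
      b <- sample(1:3, 40, TRUE)
      expect_equal(adjusted_rand_index(a, b),
                   mclust::adjustedRandIndex(a, b))
    }
  })
})

test_that("edge tiers split at 50 and 100 co-occurrences", {
  gr <- cooccurrence_graph(c("a", "a", "a", "a"), c("b", "c", "d", "e"),
                           weight = c(100, 99, 50, 49))
  tiers <- tier_edges(gr)
  expect_equal(as.character(tiers$tier[match(c(100, 99, 50, 49),
                                             tiers$weight)]),
               c("thick", "moderate", "moderate", "thin"))
  expect_false(anyNA(tiers$tier))
})

test_that("spring layout is seeded, finite, and respects symmetry", {
  gr2 <- cooccurrence_graph("a", "b")
  l1 <- spring_layout(gr2, seed = 4)
  l2 <- spring_layout(gr2, seed = 4)
  expect_identical(l1, l2)
  expect_true(all(is.finite(c(l1$x, l1$y))))

  # symmetric start: the two nodes stay mirrored about the midpoint
  sym <- spring_layout(gr2, initial = rbind(c(-1, 0), c(1, 0)))
  expect_equal(sym$x[1], -sym$x[2])
  expect_equal(sym$y[1], -sym$y[2])

  # a single node sits at the origin
  solo_posts <- annotate_corpus(make_posts("ozempic nausea"), lex)
  solo_graph <- build_cooccurrence(solo_posts)
  expect_equal(nrow(solo_graph$nodes), 0)
  one <- structure(list(nodes = tibble::tibble(ae_id = "nausea",
                                               frequency = 1L),
                        edges = solo_graph$edges),
                   class = "cooccurrence_graph")
  expect_equal(spring_layout(one), tibble::tibble(ae_id = "nausea",
                                                  x = 0, y = 0))
})

test_that("graph exports carry weights, tiers, and communities", {
  gen <- generate_corpus(planted_network_config(n_posts = 2000, seed = 23))
  ann <- annotate_corpus(gen$posts, lex)
  gr <- build_cooccurrence(ann)
  part <- louvain(gr, seed = 0)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(gr, gml, membership = part$membership)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(back), nrow(gr$nodes))
  expect_equal(igraph::gsize(back), nrow(gr$edges))
  expect_setequal(igraph::vertex_attr_names(back),
                  c("name", "frequency", "community", "id"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(gr, tsv)
  back2 <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(back2), nrow(gr$edges))
})
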