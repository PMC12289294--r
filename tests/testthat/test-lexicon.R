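lex <- load_lexicon()

test_that("the shipped adverse-event taxonomy is complete", {
  aes <- dplyr::distinct(lex$aes[, c("ae_id", "ae_category")])
  expect_equal(nrow(aes), 51)
  counts <- table(aes$ae_category)
  expect_equal(as.vector(counts[ae_categories()]),
               c(13L, 8L, 8L, 8L, 6L, 5L, 3L))
})

test_that("term matching respects word boundaries and reports spans", {
  m <- match_terms("I started Ozempic last week", c("ozempic", "ozempy"))
  expect_equal(m$span_start, 10L)
  expect_equal(m$span_end, 17L)
  expect_equal(m$matched, "Ozempic")

  # boundary rule: embedded in a longer word is not a match
  expect_equal(nrow(match_terms("ozempicious", "ozempic")), 0)
  expect_equal(nrow(match_terms("xozempic", "ozempic")), 0)
  expect_equal(nrow(match_terms("ozempic2", "ozempic")), 0)
  # punctuation and string edges are boundaries
  expect_equal(nrow(match_terms("ozempic, wow", "ozempic")), 1)

  # hyphens inside a form are literal; nested forms merge into one span
  m2 <- match_terms("GLP-1 agonist shortage", c("glp-1", "glp-1 agonist"))
  expect_equal(nrow(m2), 1)
  expect_equal(m2$span_start, 0L)
  expect_equal(m2$span_end, 13L)
})

test_that("planted term positions are recovered exactly", {
  withr::with_seed(42, {
    terms <- c("nausea", "joint pain", "hair loss")
    for (i in 1:50) {
      left <- paste(sample(c("some", "filler", "words", "before"),
                           sample(0:4, 1), replace = TRUE), collapse = " ")
      term <- sample(terms, 1)
      right <- paste(sample(c("and", "more", "after", "text"),
                            sample(0:3, 1), replace = TRUE), collapse = " ")
      msg <- trimws(paste(left, term, right))
      start <- if (nchar(left) > 0) nchar(left) + 1L else 0L
      m <- match_terms(msg, term)
      expect_equal(m$span_start, start)
      expect_equal(m$span_end, start + nchar(term))
    }
  })
})

test_that("drug category assignment has partition semantics", {
  # class terms suppressed by a specific drug
  expect_equal(assign_drug_category("GLP-1 drugs like Wegovy work", lex),
               "wegovy")
  # class category only when no specific drug matches
  expect_equal(assign_drug_category("thinking about GLP-1s", lex),
               "glp1_class")
  # earliest match wins among several specific drugs
  expect_equal(assign_drug_category("Mounjaro beats Ozempic for me", lex),
               "mounjaro")
  expect_equal(assign_drug_category("Ozempic beats Mounjaro for me", lex),
               "ozempic")
  # nothing matches
  expect_true(is.na(assign_drug_category("just a day at the beach", lex)))
  # known misspelling surface form maps to its brand
  expect_equal(assign_drug_category("my ozempy journey", lex), "ozempic")
})

test_that("matching is invariant under message case changes", {
  msgs <- c("Semaglutide gave me NAUSEA and Vomiting",
            "WEGOVY and glp-1 talk", "Joint Pain on TIRZEPATIDE")
  scrambled <- vapply(msgs, function(m) {
    ch <- strsplit(m, "")[[1]]
    up <- withr::with_seed(9, runif(length(ch)) < 0.5)
    paste(ifelse(up, toupper(ch), tolower(ch)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  expect_equal(assign_drug_category(scrambled, lex),
               assign_drug_category(msgs, lex))
  expect_equal(extract_adverse_events(scrambled, lex),
               extract_adverse_events(msgs, lex))
})

test_that("adverse-event extraction has set semantics", {
  expect_equal(extract_adverse_events("constant nausea and vomiting", lex)[[1]],
               c("nausea", "vomiting"))
  expect_equal(extract_adverse_events("nausea, nausea, nausea!", lex)[[1]],
               "nausea")
  # synonym and canonical form collapse to one id
  expect_equal(
    extract_adverse_events("hypertension aka high blood pressure", lex)[[1]],
    "hypertension")
  expect_equal(extract_adverse_events("nothing to report", lex)[[1]],
               character())
})

test_that("adding a synonym never decreases an adverse event's count", {
  msgs <- c("the queasiness is real", "nausea all day",
            "no complaints here", "queasiness and vomiting")
  base_n <- sum(vapply(extract_adverse_events(msgs, lex),
                       function(s) "nausea" %in% s, logical(1)))
  aes2 <- rbind(lex$aes,
                data.frame(ae_id = "nausea", ae_category = "gastrointestinal",
                           surface_form = "queasiness"))
  lex2 <- lex
  lex2$aes <- aes2
  new_n <- sum(vapply(extract_adverse_events(msgs, lex2),
                      function(s) "nausea" %in% s, logical(1)))
  expect_gte(new_n, base_n)
  expect_equal(new_n, 3)
})

test_that("annotation partitions the corpus and recovers planted truth", {
  posts <- make_posts(c("Wegovy week one, some nausea",
                        "no drugs mentioned at all",
                        "GLP-1 chat", "mounjaro and headache",
                        "Zepbound!", "semaglutide", "tirzepatide log",
                        "ozempic again", "random chatter", "Ozempic x2"))
  ann <- annotate_corpus(posts, lex)
  expect_equal(nrow(ann), 8)
  expect_equal(sum(table(ann$drug_category)), nrow(ann))

  # generator-labelled corpus: single drug term per message, so the
  # confusion matrix must be diagonal
  gen <- generate_corpus(generator_config(n_posts = 300, duplicate_rate = 0,
                                          seed = 5))
  ann2 <- annotate_corpus(gen$posts, lex)
  expect_equal(nrow(ann2), 300)
  truth <- gen$ledger$true_category[match(ann2$post_id, gen$ledger$post_id)]
  expect_equal(ann2$drug_category, truth)
  # and the adverse-event sets are recovered exactly
  truth_sets <- strsplit(gen$ledger$true_aes[match(ann2$post_id,
                                                   gen$ledger$post_id)], ";")
  truth_sets <- lapply(truth_sets, function(s) sort(s[nzchar(s)]))
  expect_equal(ann2$ae_ids, unname(truth_sets))
})
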