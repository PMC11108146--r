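kb2 <- prior_kb(list(
  list(name = "dbA", regulators = c("cytR", "fnr"),
       relations = data.frame(agent = "cytR", target = "crp")),
  list(name = "dbB", regulators = "cytR",
       relations = data.frame(agent = "cytR", target = "crp"))))

test_that("per-sentence votes average duplicates and keep distinct sentences", {
  inst <- tibble::tibble(
    instance_id = paste0("i", 1:4),
    sentence_id = c("a#1", "b#3", "a#2", "b#4"),
    pmid = c("a", "b", "a", "b"),
    text = c("TrpE raises trpR twice.", "TrpE raises trpR twice.",
             "Another sentence.", "Yet another sentence."),
    agent = "trpE", target = "trpR", labelled_text = "x",
    score = c(0.8, 0.6, 0.9, 0.5), label = NA_integer_)
  v <- sentence_votes(inst)
  expect_equal(nrow(v), 3)
  dup <- v[v$text == "TrpE raises trpR twice.", ]
  expect_equal(dup$vote, 0.7)              # arithmetic mean of 0.8 and 0.6
  expect_setequal(dup$pmids[[1]], c("a", "b"))
  expect_equal(sort(v$vote), c(0.5, 0.7, 0.9))
  expect_equal(sentence_votes(inst[2, ])$vote, 0.6)  # singleton mean
})

test_that("prior scores follow the three-branch rule", {
  db <- kb2$databases[[1]]
  expect_equal(prior_score("cytR", "crp", db), 3)
  expect_equal(prior_score("cytR", "deoC", db), 1)
  expect_equal(prior_score("fnr", "crp", db), 1)
  expect_equal(prior_score("marA", "crp", db), 0)
  # case-insensitive via normalization; relation agents are regulators
  expect_equal(prior_score("CytR", "CRP", db), 3)
  no_reg <- prior_kb(list(list(
    name = "d", regulators = character(0),
    relations = data.frame(agent = "cytR", target = "crp"))))$databases[[1]]
  expect_equal(prior_score("cytR", "deoC", no_reg), 1)
})

test_that("the confidence factor is CF1 + K * CF2", {
  e <- compute_cf("trpE", "trpR", votes = 0.9)
  expect_equal(e$CF, 0.9)
  e2 <- compute_cf("cytR", "crp", votes = c(0.9, 0.8), kb = kb2,
                   config = confidence_config(K = 1))
  expect_equal(e2$CF1, 1.7)
  expect_equal(e2$CF2, 6)   # relation known in both databases
  expect_equal(e2$CF, 7.7)
  k0 <- compute_cf("cytR", "crp", votes = c(0.9, 0.8), kb = kb2,
                   config = confidence_config(K = 0))
  expect_equal(k0$CF, k0$CF1)
  expect_error(compute_cf("a", "b", votes = numeric(0)), "at least one")
})

test_that("CF is monotone in votes, K, prior knowledge, and added sentences", {
  cfgs <- list(confidence_config(K = 0), confidence_config(K = 1),
               confidence_config(K = 2))
  votes <- c(0.4, 0.7)
  cf_by_k <- vapply(cfgs, function(cc) {
    compute_cf("cytR", "deoC", votes, kb2, cc)$CF
  }, numeric(1))
  expect_false(is.unsorted(cf_by_k))
  base <- compute_cf("cytR", "deoC", votes, kb2)$CF
  expect_gt(compute_cf("cytR", "deoC", c(votes, 0.5), kb2)$CF, base)
  expect_gte(compute_cf("cytR", "deoC", c(0.5, 0.7), kb2)$CF,
             compute_cf("cytR", "deoC", c(0.4, 0.7), kb2)$CF)
  # activating prior knowledge never decreases CF, and CF2 <= 3M
  expect_gte(base, compute_cf("cytR", "deoC", votes)$CF)
  expect_lte(compute_cf("cytR", "crp", votes, kb2)$CF2,
             3 * length(kb2$databases))
})

test_that("edge aggregation groups votes by directed pair", {
  inst <- tibble::tibble(
    instance_id = paste0("i", 1:3),
    sentence_id = c("a#1", "b#1", "a#2"),
    pmid = c("a", "b", "a"),
    text = c("s one.", "s two.", "s three."),
    agent = c("cytR", "cytR", "crp"), target = c("crp", "crp", "cytR"),
    labelled_text = "x", score = c(0.9, 0.8, 0.6), label = NA_integer_)
  edges <- aggregate_edges(sentence_votes(inst), kb2, confidence_config(K = 1))
  expect_equal(nrow(edges), 2)
  fwd <- edges[edges$agent == "cytR", ]
  expect_equal(fwd$n, 2L)
  expect_equal(fwd$CF, 1.7 + 6)
  expect_setequal(fwd$support_pmids[[1]], c("a", "b"))
  rev <- edges[edges$agent == "crp", ]
  expect_equal(rev$CF, 0.6)  # crp is not a known regulator
})

test_that("ROC threshold selection maximizes Youden's J with ties upward", {
  edges <- tibble::tibble(agent = c("a", "b", "c", "d"),
                          target = "x", CF = c(5, 6, 1, 2))
  gold <- data.frame(agent = c("a", "b"), target = c("x", "x"))
  expect_equal(select_gamma_roc(edges, gold), 5)

  single <- tibble::tibble(agent = c("a", "c"), target = "x", CF = c(9, 2))
  g1 <- select_gamma_roc(single, data.frame(agent = "a", target = "x"))
  expect_equal(g1, 9)  # J = 1 at the separating threshold

  expect_error(select_gamma_roc(edges, data.frame(agent = character(),
                                                  target = character())),
               "non-empty")
  expect_error(select_gamma_roc(edges,
                                data.frame(agent = c("a", "b", "c", "d"),
                                           target = "x")), "undefined")
})

test_that("threshold selection agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  edges <- tibble::tibble(agent = sprintf("g%02d", 1:40), target = "t",
                          CF = round(c(rnorm(20, 6, 2), rnorm(20, 3, 2)), 2))
  gold <- data.frame(agent = sprintf("g%02d", 1:20), target = "t")
  g <- select_gamma_roc(edges, gold)
  labels <- edges$agent %in% gold$agent
  r <- pROC::roc(labels, edges$CF, quiet = TRUE, direction = "<")
  best <- pROC::coords(r, "best", best.method = "youden",
                       transpose = FALSE)
  j_mine <- mean(edges$CF[labels] >= g) - mean(edges$CF[!labels] >= g)
  expect_equal(j_mine, max(best$sensitivity + best$specificity - 1),
               tolerance = 1e-9)
})

test_that("edges at the threshold are kept; below it dropped", {
  edges <- tibble::tibble(agent = c("a", "b", "c"), target = "x",
                          n = 1L, CF1 = c(0.87, 0.88, 0.9), CF2 = 0,
                          CF = c(0.87, 0.88, 0.9))
  kept <- filter_edges(edges, 0.88)
  expect_setequal(kept$agent, c("b", "c"))   # CF == gamma is kept
  expect_equal(nrow(filter_edges(edges, 0)), 3)
})

test_that("network export writes parseable TSV, SIF, and GraphML", {
  edges <- tibble::tibble(agent = c("A", "A"), target = c("B", "C"),
                          n = c(2L, 1L), CF1 = c(1.7, 0.9), CF2 = c(3, 0),
                          CF = c(4.7, 0.9),
                          support_pmids = list(c("p1", "p2"), "p3"),
                          support_sentences = list(c("p1#1", "p2#1"),
                                                   "p3#2"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(edges, "tsv", tsv)
  tab <- utils::read.delim(tsv)
  expect_equal(tab$CF, c(4.7, 0.9))
  expect_equal(tab$support_pmids, c("p1;p2", "p3"))

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(edges, "sif", sif)
  expect_equal(readLines(sif), c("A\tregulates\tB", "A\tregulates\tC"))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(edges, "graphml", gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_true(igraph::is_directed(g))
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), 2)
  expect_setequal(igraph::E(g)$weight, c(4.7, 0.9))
  deg <- igraph::V(g)$in_degree
  expect_setequal(deg, c(0, 1, 1))

  empty <- edges[0, ]
  export_network(empty, "graphml", gml)
  expect_equal(igraph::gorder(igraph::read_graph(gml, format = "graphml")), 0)
  expect_error(export_network(edges, "dot", gml))
})
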