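test_that("directed pair enumeration emits n*(n-1) instances in mention order", {
  lex <- make_lexicon(c("SigK", "GerE", "ykvP"))
  two <- make_sentence("SigK activates ykvP.", lex)
  inst2 <- enumerate_instances(two)
  expect_equal(nrow(inst2), 2)
  expect_equal(inst2$agent, c("SigK", "ykvP"))
  expect_equal(inst2$target, c("ykvP", "SigK"))

  three <- make_sentence("SigK and GerE jointly control ykvP.", lex)
  inst3 <- enumerate_instances(three)
  expect_equal(nrow(inst3), 6)
  expect_equal(inst3$agent[1:2], c("SigK", "SigK"))

  # repeated mention of one entity still pairs at the entity level
  rep2 <- make_sentence("SigK binds ykvP and SigK autoregulates.", lex)
  expect_equal(nrow(enumerate_instances(rep2)), 2)

  one <- make_sentence("SigK acts alone.", lex)
  expect_error(enumerate_instances(one), "fewer than two")
})

test_that("labelling masks the pair with role tags and third parties with BLANK", {
  lex <- make_lexicon(c("SigK", "GerE", "ykvP"))
  s <- make_sentence("SigK and GerE jointly control ykvP.", lex)
  lab <- render_labelled_sentence(s, "SigK", "ykvP")
  expect_equal(lab, "$GENE_AGENT# and BLANK jointly control $GENE_TARGET#.")

  two <- make_sentence("SigK activates ykvP.", lex)
  expect_equal(render_labelled_sentence(two, "SigK", "ykvP"),
               "$GENE_AGENT# activates $GENE_TARGET#.")
  expect_false(grepl("BLANK",
                     render_labelled_sentence(two, "SigK", "ykvP")))

  rep2 <- make_sentence("SigK binds ykvP and SigK autoregulates.", lex)
  lab2 <- render_labelled_sentence(rep2, "SigK", "ykvP")
  expect_equal(lab2,
               "$GENE_AGENT# binds $GENE_TARGET# and $GENE_AGENT# autoregulates.")

  expect_error(render_labelled_sentence(two, "SigK", "SigK"), "distinct")
})

test_that("instance counts match a brute-force double loop over entities", {
  set.seed(21)
  pool <- random_gene_pool(8)
  for (n in 2:6) {
    s <- random_entity_sentence(sample(pool, n))
    inst <- enumerate_instances(s)
    # oracle: explicit double loop over distinct entities
    ents <- unique(s$mentions[[1]]$norm_id)
    oracle <- 0L
    for (a in ents) for (t in ents) if (a != t) oracle <- oracle + 1L
    expect_equal(nrow(inst), oracle)
    expect_equal(oracle, n * (n - 1L))
    # exactly one agent-role and one target-role entity per instance
    expect_true(all(inst$agent != inst$target))
    expect_false(anyDuplicated(paste(inst$agent, inst$target)) > 0)
  }
})

test_that("detagging the labelled text restores the original sentence", {
  set.seed(33)
  pool <- random_gene_pool(10)
  for (i in 1:50) {
    s <- random_entity_sentence(sample(pool, sample(2:5, 1)))
    inst <- enumerate_instances(s)
    j <- sample(nrow(inst), 1)
    restored <- detag_labelled(inst$labelled_text[[j]], s,
                               inst$agent[[j]], inst$target[[j]])
    expect_identical(restored, s$text[[1]])
  }
})

test_that("fine-tuning datasets label by directed gold membership", {
  lex <- make_lexicon(c("A1x", "B2y", "C3z"))
  corpus <- rbind(
    make_sentence("A1x induces B2y.", lex, "s1",
                  gold_pairs = tibble::tibble(agent = "A1x", target = "B2y")),
    make_sentence("A1x B2y C3z were assayed.", lex, "s2",
                  gold_pairs = litgrn:::empty_pairs()),
    make_sentence("A1x binds B2y and B2y binds A1x.", lex, "s3",
                  gold_pairs = tibble::tibble(agent = c("A1x", "B2y"),
                                              target = c("B2y", "A1x"))))
  ds <- build_re_finetune_dataset(corpus)
  s1 <- ds[ds$sentence_id == "s1", ]
  expect_equal(s1$label[s1$agent == "A1x"], 1L)
  expect_equal(s1$label[s1$agent == "B2y"], 0L)
  expect_equal(sum(ds$label[ds$sentence_id == "s2"]), 0L)
  expect_equal(nrow(ds[ds$sentence_id == "s2", ]), 6L)
  expect_equal(sum(ds$label[ds$sentence_id == "s3"]), 2L)
  expect_equal(attr(ds, "class_counts")[["positive"]], 3L)

  nogold <- make_sentence("A1x induces B2y.", lex, "s9")
  expect_error(build_re_finetune_dataset(nogold), "gold")

  elim1 <- build_elim1_finetune_dataset(corpus)
  expect_equal(elim1$label, c(1L, 0L, 1L))
  expect_equal(nrow(build_elim1_finetune_dataset(corpus[0, ])), 0L)
})

test_that("k-fold splits group by sentence, balance sizes, and are seeded", {
  lex <- make_lexicon(c("A1x", "B2y"))
  corpus <- do.call(rbind, lapply(1:11, function(i) {
    make_sentence(sprintf("A1x induces B2y in assay %d.", i), lex,
                  sentence_id = sprintf("s%d", i),
                  gold_pairs = tibble::tibble(agent = "A1x", target = "B2y"))
  }))
  ds <- build_re_finetune_dataset(corpus)  # 22 instances, 11 sentences
  folds <- make_kfold_splits(ds, k = 10, seed = 7)
  test_sent_counts <- vapply(folds, function(f) {
    length(unique(ds$sentence_id[f$test]))
  }, integer(1))
  expect_equal(sort(test_sent_counts), c(rep(1L, 9), 2L))
  # disjoint, exhaustive, and sentence-grouped
  all_test <- unlist(lapply(folds, `[[`, "test"))
  expect_equal(sort(all_test), seq_len(nrow(ds)))
  for (f in folds) {
    expect_length(intersect(ds$sentence_id[f$train], ds$sentence_id[f$test]),
                  0)
  }
  expect_identical(make_kfold_splits(ds, 10, seed = 7), folds)
  expect_false(identical(make_kfold_splits(ds, 10, seed = 8), folds))
  expect_error(make_kfold_splits(ds, k = 12, seed = 1), "exceeds")

  ten <- ds[ds$sentence_id != "s11", ]
  singleton <- make_kfold_splits(ten, k = 10, seed = 1)
  expect_true(all(vapply(singleton, function(f) {
    length(unique(ten$sentence_id[f$test]))
  }, integer(1)) == 1L))
})
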