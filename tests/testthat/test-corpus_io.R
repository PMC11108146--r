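test_that("abstract records parse, deduplicate, and report malformed lines", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"pmid":"1","title":"T1","abstract":"A1"}',
    '{"pmid":"2","title":"T2","abstract":""}'), path)
  recs <- read_abstracts(path)
  expect_equal(recs$pmid, c("1", "2"))
  expect_equal(recs$abstract, c("A1", ""))

  writeLines(c(
    '{"pmid":"1","title":"first","abstract":"A"}',
    '{"pmid":"1","title":"again","abstract":"B"}'), path)
  expect_warning(recs <- read_abstracts(path), "duplicate pmid")
  expect_equal(nrow(recs), 1)
  expect_equal(recs$title, "first")

  writeLines(c(
    '{"pmid":"1","title":"T","abstract":"A"}',
    '{"pmid":"2","title":"T" "abstract"}',
    '{"pmid":"3","title":"T","abstract":"A"}'), path)
  expect_error(read_abstracts(path), "line 2")
})

test_that("abstract writer round-trips", {
  abs_in <- tibble::tibble(pmid = c("10", "11"),
                           title = c("Alpha", "Beta \"quoted\""),
                           abstract = c("sigK binds ykvP.", ""))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_abstracts(abs_in, path)
  expect_equal(read_abstracts(path), abs_in)
})

test_that("standoff corpus validates spans, surfaces, and gold pairs", {
  lex <- make_lexicon(c("sigK", "ykvP"))
  good <- make_sentence("sigK activates ykvP", lex,
                        gold_pairs = tibble::tibble(agent = "sigK",
                                                    target = "ykvP"))
  expect_equal(good$mentions[[1]]$start, c(0L, 15L))
  expect_equal(good$mentions[[1]]$end, c(4L, 19L))

  bad_span <- good
  bad_span$mentions[[1]]$end[2] <- 50L
  path <- withr::local_tempfile(fileext = ".jsonl")
  expect_error(write_standoff_corpus(bad_span, path), "bounds")

  bad_gold <- good
  bad_gold$gold_pairs[[1]] <- tibble::tibble(agent = "sigK", target = "gerE")
  expect_error(write_standoff_corpus(bad_gold, path), "absent from mentions")
})

test_that("standoff corpus round-trips field for field, including unicode", {
  lex <- make_lexicon(c("sigK", "ykvP", "σB"))
  corpus <- rbind(
    make_sentence("sigK activates ykvP strongly", lex, sentence_id = "a#1",
                  pmid = "a",
                  gold_pairs = tibble::tibble(agent = "sigK",
                                              target = "ykvP")),
    make_sentence("σB represses sigK", lex, sentence_id = "a#2",
                  pmid = "a", gold_pairs = litgrn:::empty_pairs()),
    make_sentence("no entity here", lex, sentence_id = "b#1", pmid = "b"))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_standoff_corpus(corpus, path)
  back <- read_standoff_corpus(path)
  expect_equal(back, corpus)
  # byte-stable on a second write
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  write_standoff_corpus(back, path2)
  expect_identical(readLines(path, encoding = "UTF-8"),
                   readLines(path2, encoding = "UTF-8"))

  empty <- corpus[0, ]
  write_standoff_corpus(empty, path)
  expect_equal(nrow(read_standoff_corpus(path)), 0)
})

test_that("prior-knowledge tables group by database and normalize names", {
  reg <- withr::local_tempfile(fileext = ".tsv")
  rel <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("db_name\tregulator", "dbA\tCRP"), reg)
  writeLines(c("db_name\tagent\ttarget", "dbA\tcytR\tcrp", "dbB\tcytR\tcrp"),
             rel)
  kb <- read_prior_knowledge(reg, rel)
  expect_length(kb$databases, 2)
  expect_equal(vapply(kb$databases, function(d) nrow(d$relations), 1L),
               c(1L, 1L))
  # "CRP" regulator matches relations naming "crp" after normalization
  expect_equal(prior_score("CRP", "deoC", kb$databases[[1]]), 1)

  writeLines(c("db_name\tagent\ttarget", "dbA\t\tcrp"), rel)
  expect_error(read_prior_knowledge(reg, rel), "empty agent or target")

  writeLines("db_name\tregulator", reg)
  writeLines("db_name\tagent\ttarget", rel)
  expect_length(read_prior_knowledge(reg, rel)$databases, 0)
})

test_that("prior-knowledge writer round-trips through the reader", {
  kb <- prior_kb(list(
    list(name = "dbA", regulators = c("cytR", "fnr"),
         relations = data.frame(agent = "cytR", target = "crp")),
    list(name = "dbB", regulators = character(0),
         relations = data.frame(agent = c("marA", "fis"),
                                target = c("marB", "crp")))))
  reg <- withr::local_tempfile(fileext = ".tsv")
  rel <- withr::local_tempfile(fileext = ".tsv")
  write_prior_knowledge(kb, reg, rel)
  back <- read_prior_knowledge(reg, rel)
  expect_equal(back$databases, kb$databases)
})

test_that("word lists skip comments and blank lines and fold case", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# header", "Protein", "", "gene  # trailing", "FACTOR"), path)
  expect_equal(read_word_list(path), c("protein", "gene", "factor"))
})

test_that("gene lexicon TSV round-trips and rejects empty surfaces", {
  lex <- tibble::tibble(surface = c("sigK", "sigma factor SigK"),
                        norm_id = c("sigK", "sigK"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_lexicon(lex, path)
  expect_equal(read_gene_lexicon(path), lex)
})
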