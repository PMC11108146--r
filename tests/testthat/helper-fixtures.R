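# Small in-code fixtures shared across test files.

make_lexicon <- function(names) {
  tibble::tibble(surface = names, norm_id = names)
}

# One-row sentence-corpus tibble with mentions annotated by the lexicon stub.
make_sentence <- function(text, lexicon, sentence_id = "s1", pmid = "p1",
                          gold_pairs = NULL) {
  litgrn:::new_sentence_corpus(
    sentence_id = sentence_id, pmid = pmid, text = text,
    mentions = list(stub_annotate(text, lexicon)),
    gold_pairs = list(gold_pairs))
}

# Invert the anonymized labelling: walk the sentence's gene mentions left to
# right and substitute each one's original surface back for its role token.
detag_labelled <- function(labelled, sentence, agent, target) {
  men <- sentence$mentions[[1]]
  men <- men[men$type == "gene/protein", , drop = FALSE]
  men <- men[order(men$start), , drop = FALSE]
  out <- labelled
  for (i in seq_len(nrow(men))) {
    token <- if (men$norm_id[[i]] == agent) "$GENE_AGENT#"
             else if (men$norm_id[[i]] == target) "$GENE_TARGET#"
             else "BLANK"
    out <- sub(token, men$surface[[i]], out, fixed = TRUE)
  }
  out
}

# Deterministic pool of gene-like names for random-sentence tests.
random_gene_pool <- function(n) {
  vapply(seq_len(n), function(i) {
    paste0(paste(sample(letters, 3, replace = TRUE), collapse = ""),
           sample(LETTERS, 1), i)
  }, character(1))
}

# A random sentence mentioning the given entities once each, with filler text.
random_entity_sentence <- function(entities, id = "s1", pmid = "p1") {
  fill <- c("modulates the level of", "was observed together with",
            "acts upstream of", "correlates with abundance of",
            "and", "as well as")
  parts <- entities[1]
  for (i in seq_along(entities)[-1]) {
    parts <- c(parts, sample(fill, 1), entities[i])
  }
  text <- paste0("In this assay ", paste(parts, collapse = " "),
                 " under controlled conditions.")
  make_sentence(text, make_lexicon(entities), sentence_id = id, pmid = pmid)
}
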