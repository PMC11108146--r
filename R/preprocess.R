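#' Default search keyword phrase
#'
#' The keyword phrase appended to the organism name when building the
#' literature search query for transcriptional-regulation abstracts.
#'
#' @return A single string.
#' @export
default_keywords <- function() "gene expression regulation transcriptional"

#' Query specification for abstract retrieval
#'
#' @param organism Binomial (or single-word) organism name; mandatory.
#' @param keywords Keyword phrase; defaults to [default_keywords()].
#' @param retmax Maximum number of documents to retrieve (>= 1).
#' @return An object of class `query_spec`.
#' @export
query_spec <- function(organism, keywords = default_keywords(),
                       retmax = 1000L) {
  if (missing(organism) || is.null(organism) || !nzchar(trimws(organism))) {
    stop("organism is mandatory in a query specification", call. = FALSE)
  }
  stopifnot(nzchar(keywords), retmax >= 1)
  structure(list(organism = trimws(organism), keywords = keywords,
                 retmax = as.integer(retmax)), class = "query_spec")
}

#' Surface forms of an organism name
#'
#' A binomial "Genus species" yields the full form plus the abbreviated
#' forms "G. species" and "G species"; a single-word name is returned as a
#' singleton. Downstream matching is case-insensitive.
#'
#' @param organism Organism name.
#' @return Character vector of surface forms.
#' @export
organism_name_forms <- function(organism) {
  organism <- trimws(organism)
  words <- strsplit(organism, "[[:space:]]+")[[1]]
  if (length(words) < 2) return(organism)
  initial <- substr(words[[1]], 1, 1)
  rest <- paste(words[-1], collapse = " ")
  c(organism, paste0(initial, ". ", rest), paste0(initial, " ", rest))
}

#' Build the literature search query string
#'
#' The query is the organism name (optionally preceded by its undotted
#' abbreviation, as used for well-known genera) followed by the keyword
#' phrase, whitespace-joined.
#'
#' @param spec A `query_spec`.
#' @param expand_abbreviation Prepend the "G species" abbreviated form
#'   before the full name.
#' @return Query string.
#' @export
build_query <- function(spec, expand_abbreviation = FALSE) {
  stopifnot(inherits(spec, "query_spec"))
  forms <- organism_name_forms(spec$organism)
  name_part <- if (expand_abbreviation && length(forms) > 1) {
    paste(forms[[3]], forms[[1]])
  } else {
    forms[[1]]
  }
  paste(name_part, spec$keywords)
}

#' Filter abstracts by organism mention
#'
#' A record is kept iff its title or abstract contains any of the organism
#' surface forms (case-insensitive substring; abbreviated forms legitimately
#' end at punctuation, so no whole-word constraint is applied).
#'
#' @param abstracts Abstract tibble (`pmid`, `title`, `abstract`).
#' @param forms Non-empty character vector of surface forms (see
#'   [organism_name_forms()]).
#' @return The kept subset of `abstracts`.
#' @export
filter_abstracts_by_organism <- function(abstracts, forms) {
  stopifnot(length(forms) > 0)
  hay <- tolower(paste(abstracts$title, abstracts$abstract))
  keep <- rep(FALSE, nrow(abstracts))
  for (f in forms) keep <- keep | grepl(tolower(f), hay, fixed = TRUE)
  abstracts[keep, , drop = FALSE]
}

# Tokens before a period that never end a sentence.
sentence_abbreviations <- function() {
  c("cf", "e.g", "i.e", "sp", "spp", "al", "fig", "figs", "vs", "etc",
    "ca", "approx", "no")
}

#' Split an abstract into sentences
#'
#' Rule-based, abbreviation-aware splitter: a run of `.`, `!` or `?`
#' followed by whitespace ends a sentence unless the preceding token is a
#' single capital letter (genus initials such as "E." or "B.") or a known
#' abbreviation ("cf.", "e.g.", "i.e.", "sp.", "spp.", "et al.", ...).
#' Concatenating the returned sentence texts (modulo inter-sentence
#' whitespace) reconstructs the abstract. Sentence ids are derived from the
#' pmid and are deterministic.
#'
#' @param record One-row abstract tibble, or a list with `pmid` and
#'   `abstract`.
#' @return A sentence-corpus tibble with empty mentions.
#' @export
split_sentences <- function(record) {
  pmid <- record$pmid[[1]]
  text <- record$abstract[[1]]
  if (is.na(text) || !nzchar(trimws(text))) return(new_sentence_corpus())
  hits <- gregexpr("[.!?]+(?=[[:space:]])", text, perl = TRUE)[[1]]
  cuts <- integer(0)
  if (hits[1] != -1) {
    len <- attr(hits, "match.length")
    abbrev <- sentence_abbreviations()
    for (j in seq_along(hits)) {
      endpos <- hits[j] + len[j] - 1L
      before <- substr(text, 1, hits[j] - 1L)
      tok <- sub("^.*?([^[:space:]]*)$", "\\1", before)
      tok <- tolower(gsub("[()\\[\\]\"']", "", tok, perl = TRUE))
      if (substr(text, endpos, endpos) == "." &&
          (tok %in% abbrev || grepl("^[a-z]$", tok))) next
      cuts <- c(cuts, endpos)
    }
  }
  bounds <- c(0L, cuts, nchar(text))
  sentences <- character(0)
  for (j in seq_len(length(bounds) - 1L)) {
    piece <- trimws(substr(text, bounds[j] + 1L, bounds[j + 1L]))
    if (nzchar(piece)) sentences <- c(sentences, piece)
  }
  n <- length(sentences)
  new_sentence_corpus(sentence_id = sprintf("%s#%d", pmid, seq_len(n)),
                      pmid = rep(pmid, n), text = sentences,
                      mentions = rep(list(empty_mentions()), n),
                      gold_pairs = rep(list(NULL), n))
}

#' Split every abstract in a collection into sentences
#'
#' @param abstracts Abstract tibble.
#' @return A sentence-corpus tibble.
#' @export
split_sentences_all <- function(abstracts) {
  parts <- lapply(seq_len(nrow(abstracts)),
                  function(i) split_sentences(abstracts[i, ]))
  if (length(parts) == 0) return(new_sentence_corpus())
  do.call(rbind, parts)
}

#' Default interaction trigger stems
#'
#' Word stems signalling a regulatory interaction; shared by the rule-based
#' relevance scorer and the rule-based relation scorer.
#'
#' @return Character vector of stems.
#' @export
default_trigger_stems <- function() {
  c("regulat", "repress", "activat", "induc", "bind", "bound", "express",
    "transcrib")
}

#' Rule-based sentence relevance scorer
#'
#' Deterministic stand-in for a fine-tuned sentence classifier: a sentence
#' scores 1 when it contains an interaction trigger stem, else 0. The
#' contract (`score_text(texts)` returning values in [0,1]) accepts any
#' model-backed implementation in its place.
#'
#' @param triggers Character vector of trigger stems.
#' @return An object of class `relevance_scorer`.
#' @export
rule_relevance_scorer <- function(triggers = default_trigger_stems()) {
  pat <- paste0("\\b(", paste(triggers, collapse = "|"), ")")
  structure(list(
    name = "rule-stub",
    score_text = function(texts) {
      as.numeric(grepl(pat, texts, ignore.case = TRUE, perl = TRUE))
    }), class = "relevance_scorer")
}

#' Sentence eliminator 1: drop sentences without regulatory context
#'
#' Keeps a sentence iff the relevance scorer assigns it a score at or above
#' `cutoff`. The returned partition is exhaustive and disjoint.
#'
#' @param sentences Sentence-corpus tibble.
#' @param scorer A `relevance_scorer`.
#' @param cutoff Decision threshold in [0,1] on the scorer's soft output.
#' @return `list(kept =, removed =)` sentence tibbles.
#' @export
eliminate_nonregulatory <- function(sentences, scorer, cutoff = 0.5) {
  stopifnot(inherits(scorer, "relevance_scorer"),
            cutoff >= 0, cutoff <= 1)
  if (nrow(sentences) == 0) {
    return(list(kept = sentences, removed = sentences))
  }
  scores <- scorer$score_text(sentences$text)
  stopifnot(all(scores >= 0 & scores <= 1))
  keep <- scores >= cutoff
  list(kept = sentences[keep, , drop = FALSE],
       removed = sentences[!keep, , drop = FALSE])
}

#' Sentence eliminator 2: drop sentences with fewer than two entities
#'
#' Annotates each sentence with the provider and keeps it iff it carries at
#' least two gene/protein mentions with distinct normalized ids (two
#' mentions of the same gene cannot form a directed pair). Kept sentences
#' carry their mentions. A provider failure removes the sentence
#' (fail-closed) with a warning.
#'
#' @param sentences Sentence-corpus tibble.
#' @param provider A `ner_provider`.
#' @return `list(kept =, removed =)` sentence tibbles; `kept` rows carry
#'   mentions.
#' @export
eliminate_by_entity_count <- function(sentences, provider) {
  stopifnot(inherits(provider, "ner_provider"))
  if (nrow(sentences) == 0) {
    return(list(kept = sentences, removed = sentences))
  }
  keep <- logical(nrow(sentences))
  mentions <- sentences$mentions
  for (i in seq_len(nrow(sentences))) {
    men <- tryCatch(provider$annotate(sentences$text[[i]]), error = function(e) e)
    if (inherits(men, "error")) {
      warning(sprintf("NER failed on sentence '%s' (%s); sentence removed",
                      sentences$sentence_id[[i]], conditionMessage(men)),
              call. = FALSE)
      keep[i] <- FALSE
      next
    }
    genes <- men[men$type == "gene/protein", , drop = FALSE]
    keep[i] <- length(unique(genes$norm_id)) >= 2
    mentions[[i]] <- men
  }
  sentences$mentions <- mentions
  list(kept = sentences[keep, , drop = FALSE],
       removed = sentences[!keep, , drop = FALSE])
}
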