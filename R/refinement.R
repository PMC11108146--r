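#' Default stoplist of non-entity words
#'
#' Frequent descriptive words removed from multi-word entity phrases before
#' word-level entity lookup; cheap to apply and replaceable via config.
#'
#' @return Character vector (lower-case).
#' @export
default_stoplist <- function() {
  read_word_list(system.file("extdata", "stoplist.txt", package = "litgrn",
                             mustWork = TRUE))
}

#' Bundled common-English word lexicon
#'
#' Lower-cased list of common English and biomedical descriptive words used
#' by the misspelling heuristic: a word absent from this lexicon is taken to
#' be a gene/protein name.
#'
#' @return Character vector (lower-case).
#' @export
default_english_lexicon <- function() {
  read_word_list(system.file("extdata", "english_words.txt",
                             package = "litgrn", mustWork = TRUE))
}

#' Configuration for entity-name refinement
#'
#' @param provider A `ner_provider` used for word-level lookup.
#' @param stoplist Lower-cased non-entity words.
#' @param english_lexicon Lower-cased common-word lexicon.
#' @return An object of class `refinement_config`.
#' @export
refinement_config <- function(provider, stoplist = default_stoplist(),
                              english_lexicon = default_english_lexicon()) {
  stopifnot(inherits(provider, "ner_provider"))
  structure(list(provider = provider, stoplist = tolower(stoplist),
                 english_lexicon = tolower(english_lexicon)),
            class = "refinement_config")
}

strip_word_punct <- function(w) gsub("^[[:punct:]]+|[[:punct:]]+$", "", w)

#' Misspelling heuristic for gene-likeness
#'
#' Gene and protein names are built from letters, digits and symbols that
#' rarely form dictionary words, so a word a spell-checker would flag
#' (absent from the common-word lexicon) is treated as a gene/protein name,
#' while a correctly spelt word is assumed descriptive. Words containing a
#' digit or an internal capital are gene-like regardless of the lexicon.
#'
#' @param word Single word, no whitespace.
#' @param lexicon Lower-cased common-word lexicon.
#' @return `TRUE` when the word looks like a gene/protein name.
#' @export
is_gene_like_word <- function(word, lexicon = default_english_lexicon()) {
  stopifnot(nzchar(word), !grepl("[[:space:]]", word))
  w <- strip_word_punct(word)
  if (!nzchar(w)) return(FALSE)
  if (grepl("[0-9]", w)) return(TRUE)
  if (grepl(".[A-Z]", w)) return(TRUE)
  !(tolower(w) %in% lexicon)
}

#' Refine a multi-word entity phrase to a bare gene/protein name
#'
#' Pipeline: (1) a single-word phrase is returned as-is; (2) stoplist words
#' are removed (cheaply, before any entity lookup); (3) the remaining words
#' are looked up one by one with the word-level provider and recognized
#' names collected; (4) if none is recognized, the misspelling heuristic
#' ([is_gene_like_word()]) is applied to the remaining words; (5) the first
#' surviving word in original order is returned, or `NA` when none survives
#' (the relation is then incomplete and must be dropped).
#'
#' @param phrase Entity surface phrase (non-empty).
#' @param config A `refinement_config`.
#' @return The refined name, or `NA_character_`.
#' @export
refine_entity_name <- function(phrase, config) {
  stopifnot(inherits(config, "refinement_config"), nzchar(phrase))
  words <- strsplit(trimws(phrase), "[[:space:]]+")[[1]]
  if (length(words) == 1) return(words)
  clean <- strip_word_punct(words)
  keep <- nzchar(clean) & !(tolower(clean) %in% config$stoplist)
  words <- clean[keep]
  if (length(words) == 0) return(NA_character_)
  recognized <- vapply(words, function(w) {
    !is.null(annotate_word(w, config$provider))
  }, logical(1))
  survivors <- if (any(recognized)) {
    words[recognized]
  } else {
    words[vapply(words, is_gene_like_word, logical(1),
                 lexicon = config$english_lexicon)]
  }
  if (length(survivors) == 0) return(NA_character_)
  if (length(survivors) > 1) {
    warning(sprintf("phrase '%s': multiple candidate entity words (%s); keeping the first",
                    phrase, paste(survivors, collapse = ", ")),
            call. = FALSE)
  }
  survivors[[1]]
}

# Map a refined word to its canonical id when the provider knows it.
canonical_name <- function(word, provider) {
  if (is.na(word)) return(NA_character_)
  m <- annotate_word(word, provider)
  if (is.null(m)) word else m$norm_id[[1]]
}

#' Refine the endpoint names of positive relation instances
#'
#' Both endpoint names are refined with [refine_entity_name()] and, when the
#' provider recognizes the surviving word, normalized to its canonical id.
#' Instances where either endpoint refines to nothing (or both endpoints
#' collapse to the same name) are dropped with a warning; duplicates (same
#' sentence, agent, target after refinement) are merged, averaging their
#' scores.
#'
#' @param positives Positive instance tibble.
#' @param config A `refinement_config`.
#' @return Refined instance tibble.
#' @export
refine_relations <- function(positives, config) {
  stopifnot(inherits(config, "refinement_config"))
  if (nrow(positives) == 0) return(positives)
  refit <- function(name) {
    canonical_name(refine_entity_name(name, config), config$provider)
  }
  cache <- new.env(parent = emptyenv())
  refit_cached <- function(name) {
    if (is.null(cache[[name]])) cache[[name]] <- refit(name)
    cache[[name]]
  }
  agent <- vapply(positives$agent, refit_cached, character(1),
                  USE.NAMES = FALSE)
  target <- vapply(positives$target, refit_cached, character(1),
                   USE.NAMES = FALSE)
  drop <- is.na(agent) | is.na(target) | agent == target
  if (any(drop)) {
    warning(sprintf("dropping %d incomplete relation instance(s) after refinement",
                    sum(drop)), call. = FALSE)
  }
  out <- positives[!drop, , drop = FALSE]
  out$agent <- agent[!drop]
  out$target <- target[!drop]
  key <- paste(out$sentence_id, out$agent, out$target, sep = "\r")
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    score <- tapply(out$score, key, mean)
    merged <- out[first, , drop = FALSE]
    merged$score <- as.numeric(score[paste(merged$sentence_id, merged$agent,
                                           merged$target, sep = "\r")])
    out <- merged
  }
  out
}
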