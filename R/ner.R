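#' Dictionary-based named-entity provider
#'
#' A deterministic gene/protein recognizer backed by a lexicon of
#' `(surface, norm_id)` entries. Matching is case-insensitive at word
#' boundaries, longest match first, then leftmost; overlapping candidates
#' are discarded. It stands behind the same provider contract as an
#' external neural NER/NEN service adapter, so tests and hermetic runs use
#' it as a gold oracle (probability fixed at 1.0).
#'
#' @param lexicon Tibble with columns `surface`, `norm_id` (see
#'   [read_gene_lexicon()]).
#' @return An object of class `ner_provider` with elements `annotate(text)`
#'   and `annotate_word(token)`.
#' @export
lexicon_ner <- function(lexicon) {
  stopifnot(nrow(lexicon) > 0, all(nzchar(lexicon$surface)))
  lex <- lexicon[order(-nchar(lexicon$surface), lexicon$surface), ,
                 drop = FALSE]
  word_map <- stats::setNames(lexicon$norm_id, tolower(lexicon$surface))
  provider <- list(
    name = "lexicon-stub",
    annotate = function(text) stub_annotate(text, lex, presorted = TRUE),
    annotate_word = function(token) {
      if (!nzchar(token) || grepl("[[:space:]]", token)) return(NULL)
      norm <- unname(word_map[tolower(token)])
      if (is.na(norm)) return(NULL)
      tibble::tibble(start = 0L, end = nchar(token), surface = token,
                     type = "gene/protein", prob = 1.0, norm_id = norm)
    })
  structure(provider, class = "ner_provider")
}

#' Annotate a sentence with a gene lexicon
#'
#' Returns all non-overlapping longest matches left to right, each typed
#' `gene/protein` with probability 1.0 and the lexicon's normalized id.
#' Offsets are 0-based half-open over `text`. Matches must fall on word
#' boundaries (not flanked by letters or digits) so gene names embedded in
#' longer words are not tagged.
#'
#' @param text Sentence text.
#' @param lexicon Tibble with columns `surface`, `norm_id`.
#' @param presorted Internal: lexicon already sorted longest-first.
#' @return A mention tibble (possibly empty) sorted by `start`.
#' @export
stub_annotate <- function(text, lexicon, presorted = FALSE) {
  stopifnot(nrow(lexicon) > 0)
  if (!presorted) {
    lexicon <- lexicon[order(-nchar(lexicon$surface), lexicon$surface), ,
                       drop = FALSE]
  }
  cand <- list()
  for (i in seq_len(nrow(lexicon))) {
    surf <- lexicon$surface[[i]]
    pat <- paste0("(?<![A-Za-z0-9])",
                  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", surf),
                  "(?![A-Za-z0-9])")
    m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    for (j in seq_along(m)) {
      cand[[length(cand) + 1]] <- c(start = m[j] - 1L, len = len[j], row = i)
    }
  }
  if (length(cand) == 0) return(empty_mentions())
  cand <- do.call(rbind, cand)
  # longest first, then leftmost, then lexicon order; greedy non-overlap
  cand <- cand[order(-cand[, "len"], cand[, "start"], cand[, "row"]), ,
               drop = FALSE]
  taken <- logical(nchar(text))
  keep <- logical(nrow(cand))
  for (j in seq_len(nrow(cand))) {
    span <- seq.int(cand[j, "start"] + 1, cand[j, "start"] + cand[j, "len"])
    if (!any(taken[span])) {
      taken[span] <- TRUE
      keep[j] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand[, "start"]), , drop = FALSE]
  start <- as.integer(cand[, "start"])
  end <- as.integer(cand[, "start"] + cand[, "len"])
  tibble::tibble(start = start, end = end,
                 surface = substring(text, start + 1, end),
                 type = "gene/protein", prob = 1.0,
                 norm_id = lexicon$norm_id[cand[, "row"]])
}

#' Word-level entity lookup
#'
#' Used by the refinement stage to test whether a single word of a
#' multi-word entity phrase is itself a recognized gene/protein name.
#'
#' @param token A single word (no whitespace).
#' @param provider A `ner_provider`.
#' @return A one-row mention tibble, or `NULL` when unrecognized.
#' @export
annotate_word <- function(token, provider) {
  stopifnot(inherits(provider, "ner_provider"))
  if (!nzchar(token)) return(NULL)
  if (grepl("[[:space:]]", token)) {
    stop("annotate_word expects a single token without whitespace",
         call. = FALSE)
  }
  provider$annotate_word(token)
}
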