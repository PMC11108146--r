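#' Read abstract records from a JSON Lines file
#'
#' Each line holds one JSON object with keys `pmid`, `title` and `abstract`.
#' Duplicate `pmid`s are collapsed keeping the first occurrence, with a
#' warning; an empty abstract is allowed (downstream filters flag the record
#' as unusable).
#'
#' @param path Path to a JSON Lines file.
#' @return A tibble with columns `pmid`, `title`, `abstract`.
#' @export
read_abstracts <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) NULL)
    if (is.null(obj) || !all(c("pmid", "title", "abstract") %in% names(obj)) ||
        !nzchar(as.character(obj$pmid))) {
      stop(sprintf("malformed abstract record at line %d of '%s'", i, path),
           call. = FALSE)
    }
    recs[[i]] <- tibble::tibble(pmid = as.character(obj$pmid),
                                title = as.character(obj$title),
                                abstract = as.character(obj$abstract))
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    return(tibble::tibble(pmid = character(), title = character(),
                          abstract = character()))
  }
  dup <- duplicated(out$pmid)
  if (any(dup)) {
    warning(sprintf("dropping %d duplicate pmid record(s): %s", sum(dup),
                    paste(unique(out$pmid[dup]), collapse = ", ")),
            call. = FALSE)
    out <- out[!dup, , drop = FALSE]
  }
  out
}

#' Write abstract records to a JSON Lines file
#'
#' @param abstracts Tibble with columns `pmid`, `title`, `abstract`.
#' @param path Output path.
#' @export
write_abstracts <- function(abstracts, path) {
  lines <- vapply(seq_len(nrow(abstracts)), function(i) {
    jsonlite::toJSON(list(pmid = abstracts$pmid[[i]],
                          title = abstracts$title[[i]],
                          abstract = abstracts$abstract[[i]]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(enc2utf8(lines), path, useBytes = TRUE)
  invisible(path)
}

empty_mentions <- function() {
  tibble::tibble(start = integer(), end = integer(), surface = character(),
                 type = character(), prob = double(), norm_id = character())
}

empty_pairs <- function() {
  tibble::tibble(agent = character(), target = character())
}

new_sentence_corpus <- function(sentence_id = character(), pmid = character(),
                                text = character(), mentions = list(),
                                gold_pairs = list()) {
  tibble::tibble(sentence_id = sentence_id, pmid = pmid, text = text,
                 mentions = mentions, gold_pairs = gold_pairs)
}

validate_mentions <- function(mentions, text, sentence_id) {
  if (nrow(mentions) == 0) return(invisible(TRUE))
  n <- nchar(text)
  ok <- mentions$start >= 0 & mentions$start < mentions$end & mentions$end <= n
  if (!all(ok)) {
    stop(sprintf("sentence '%s': mention span outside text bounds",
                 sentence_id), call. = FALSE)
  }
  slice <- substr(rep(text, nrow(mentions)), mentions$start + 1, mentions$end)
  if (!all(slice == mentions$surface)) {
    stop(sprintf("sentence '%s': mention surface does not match text slice",
                 sentence_id), call. = FALSE)
  }
  if (any(mentions$prob < 0 | mentions$prob > 1)) {
    stop(sprintf("sentence '%s': mention probability outside [0,1]",
                 sentence_id), call. = FALSE)
  }
  m <- mentions[order(mentions$start), , drop = FALSE]
  if (nrow(m) > 1 && any(m$start[-1] < m$end[-nrow(m)])) {
    stop(sprintf("sentence '%s': overlapping mentions", sentence_id),
         call. = FALSE)
  }
  invisible(TRUE)
}

validate_sentence_record <- function(rec) {
  validate_mentions(rec$mentions[[1]], rec$text, rec$sentence_id)
  gp <- rec$gold_pairs[[1]]
  if (!is.null(gp) && nrow(gp) > 0) {
    ids <- rec$mentions[[1]]$norm_id
    missing <- setdiff(unique(c(gp$agent, gp$target)), ids)
    if (length(missing) > 0) {
      stop(sprintf("sentence '%s': gold pair names entity absent from mentions: %s",
                   rec$sentence_id, paste(missing, collapse = ", ")),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read a sentence standoff corpus from JSON Lines
#'
#' One object per line with keys `sentence_id`, `pmid`, `text`, `mentions`
#' (array of objects with `start`, `end`, `surface`, `type`, `prob`,
#' `norm_id`; offsets 0-based half-open over `text`) and optional
#' `gold_pairs` (array of `[agent, target]` pairs). Records violating the
#' mention/gold-pair invariants are rejected with the offending
#' `sentence_id`.
#'
#' @param path Path to a JSON Lines file.
#' @return A sentence-corpus tibble with list columns `mentions` and
#'   `gold_pairs` (`NULL` entry when the key was absent).
#' @export
read_standoff_corpus <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(obj) || !all(c("sentence_id", "pmid", "text") %in% names(obj))) {
      stop(sprintf("malformed sentence record at line %d of '%s'", i, path),
           call. = FALSE)
    }
    men <- empty_mentions()
    if (length(obj$mentions) > 0) {
      men <- do.call(rbind, lapply(obj$mentions, function(m) {
        tibble::tibble(start = as.integer(m$start), end = as.integer(m$end),
                       surface = as.character(m$surface),
                       type = as.character(m$type), prob = as.double(m$prob),
                       norm_id = as.character(m$norm_id))
      }))
    }
    gp <- NULL
    if (!is.null(obj$gold_pairs)) {
      gp <- if (length(obj$gold_pairs) == 0) empty_pairs() else
        do.call(rbind, lapply(obj$gold_pairs, function(p) {
          tibble::tibble(agent = as.character(p[[1]]),
                         target = as.character(p[[2]]))
        }))
    }
    recs[[i]] <- new_sentence_corpus(as.character(obj$sentence_id),
                                     as.character(obj$pmid),
                                     as.character(obj$text),
                                     list(men), list(gp))
  }
  out <- if (length(recs) == 0) new_sentence_corpus() else do.call(rbind, recs)
  if (anyDuplicated(out$sentence_id)) {
    stop(sprintf("duplicate sentence_id in corpus: %s",
                 out$sentence_id[duplicated(out$sentence_id)][1]),
         call. = FALSE)
  }
  for (i in seq_len(nrow(out))) validate_sentence_record(out[i, ])
  out
}

#' Write a sentence standoff corpus to JSON Lines
#'
#' Inverse of [read_standoff_corpus()]; `read(write(x))` reproduces `x`
#' field for field.
#'
#' @param records Sentence-corpus tibble.
#' @param path Output path.
#' @export
write_standoff_corpus <- function(records, path) {
  for (i in seq_len(nrow(records))) validate_sentence_record(records[i, ])
  lines <- vapply(seq_len(nrow(records)), function(i) {
    men <- records$mentions[[i]]
    obj <- list(sentence_id = records$sentence_id[[i]],
                pmid = records$pmid[[i]],
                text = records$text[[i]],
                mentions = lapply(seq_len(nrow(men)), function(j) {
                  list(start = men$start[[j]], end = men$end[[j]],
                       surface = men$surface[[j]], type = men$type[[j]],
                       prob = men$prob[[j]], norm_id = men$norm_id[[j]])
                }))
    gp <- records$gold_pairs[[i]]
    if (!is.null(gp)) {
      obj$gold_pairs <- lapply(seq_len(nrow(gp)),
                               function(j) list(gp$agent[[j]], gp$target[[j]]))
    }
    jsonlite::toJSON(obj, auto_unbox = TRUE)
  }, character(1))
  writeLines(enc2utf8(lines), path, useBytes = TRUE)
  invisible(path)
}

#' Normalize an entity name
#'
#' Case-fold, strip surrounding punctuation, and collapse internal
#' whitespace. Relations extracted from different papers are grouped by
#' this normalized form.
#'
#' @param x Character vector of entity names.
#' @return Normalized character vector.
#' @export
normalize_entity_name <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", x)
  gsub("[[:space:]]+", " ", x)
}

#' Read a prior-knowledge base from two TSV tables
#'
#' `regulators_path` has header columns `db_name`, `regulator`;
#' `relations_path` has `db_name`, `agent`, `target`. Names are normalized
#' with [normalize_entity_name()] and relations grouped per database. Every
#' relation's agent is implicitly a regulator for that database.
#'
#' @param regulators_path,relations_path Paths to the TSV tables.
#' @return An object of class `prior_kb`.
#' @export
read_prior_knowledge <- function(regulators_path, relations_path) {
  reg <- utils::read.delim(regulators_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  rel <- utils::read.delim(relations_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  stopifnot(all(c("db_name", "regulator") %in% names(reg)),
            all(c("db_name", "agent", "target") %in% names(rel)))
  if (nrow(rel) > 0 && any(!nzchar(trimws(rel$agent)) |
                           !nzchar(trimws(rel$target)))) {
    stop("relation row with empty agent or target", call. = FALSE)
  }
  dbs <- sort(unique(c(reg$db_name, rel$db_name)))
  databases <- lapply(dbs, function(d) {
    list(name = d,
         regulators = unique(normalize_entity_name(
           reg$regulator[reg$db_name == d])),
         relations = tibble::tibble(
           agent = normalize_entity_name(rel$agent[rel$db_name == d]),
           target = normalize_entity_name(rel$target[rel$db_name == d])))
  })
  structure(list(databases = databases), class = "prior_kb")
}

#' Construct a prior-knowledge base in memory
#'
#' @param databases List of `list(name, regulators, relations)` entries where
#'   `relations` is a data frame with columns `agent`, `target`.
#' @return An object of class `prior_kb`.
#' @export
prior_kb <- function(databases = list()) {
  databases <- lapply(databases, function(db) {
    list(name = db$name,
         regulators = unique(normalize_entity_name(db$regulators)),
         relations = tibble::tibble(
           agent = normalize_entity_name(db$relations$agent),
           target = normalize_entity_name(db$relations$target)))
  })
  structure(list(databases = databases), class = "prior_kb")
}

#' @export
print.prior_kb <- function(x, ...) {
  cat(sprintf("<prior_kb> %d database(s)\n", length(x$databases)))
  for (db in x$databases) {
    cat(sprintf("  %s: %d regulators, %d relations\n", db$name,
                length(db$regulators), nrow(db$relations)))
  }
  invisible(x)
}

#' Write a prior-knowledge base to the two-table TSV layout
#'
#' @param kb A `prior_kb` object.
#' @param regulators_path,relations_path Output paths.
#' @export
write_prior_knowledge <- function(kb, regulators_path, relations_path) {
  reg <- do.call(rbind, c(list(data.frame(db_name = character(),
                                          regulator = character())),
    lapply(kb$databases, function(db) {
      if (length(db$regulators) == 0) return(NULL)
      data.frame(db_name = db$name, regulator = db$regulators)
    })))
  rel <- do.call(rbind, c(list(data.frame(db_name = character(),
                                          agent = character(),
                                          target = character())),
    lapply(kb$databases, function(db) {
      if (nrow(db$relations) == 0) return(NULL)
      data.frame(db_name = db$name, agent = db$relations$agent,
                 target = db$relations$target)
    })))
  utils::write.table(reg, regulators_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(rel, relations_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(kb)
}

#' Read a plain-text word list
#'
#' One token per line; `#` starts a comment; blank lines ignored. Words are
#' lower-cased (stoplists and English lexicons are case-insensitive).
#'
#' @param path Path to the word list.
#' @return Character vector of lower-cased words.
#' @export
read_word_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(tolower(lines[nzchar(lines)]))
}

#' Read a gene lexicon from TSV
#'
#' Header columns `surface`, `norm_id`. Matching downstream is
#' case-insensitive, longest match first.
#'
#' @param path Path to the lexicon TSV.
#' @return A tibble with columns `surface`, `norm_id`.
#' @export
read_gene_lexicon <- function(path) {
  lex <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  stopifnot(all(c("surface", "norm_id") %in% names(lex)))
  if (any(!nzchar(lex$surface))) {
    stop("gene lexicon contains an empty surface form", call. = FALSE)
  }
  tibble::tibble(surface = lex$surface, norm_id = lex$norm_id)
}

#' Write a gene lexicon to TSV
#'
#' @param lexicon Tibble with columns `surface`, `norm_id`.
#' @param path Output path.
#' @export
write_gene_lexicon <- function(lexicon, path) {
  utils::write.table(as.data.frame(lexicon[, c("surface", "norm_id")]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
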