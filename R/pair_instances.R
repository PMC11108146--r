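gene_agent_tag <- function() "$GENE_AGENT#"
gene_target_tag <- function() "$GENE_TARGET#"
blank_tag <- function() "BLANK"

empty_instances <- function() {
  tibble::tibble(instance_id = character(), sentence_id = character(),
                 pmid = character(), text = character(), agent = character(),
                 target = character(), labelled_text = character(),
                 score = double(), label = integer())
}

distinct_entities_in_order <- function(mentions) {
  genes <- mentions[mentions$type == "gene/protein", , drop = FALSE]
  genes <- genes[order(genes$start), , drop = FALSE]
  unique(genes$norm_id)
}

#' Render the anonymized labelled sentence for one directed pair
#'
#' Every mention of the agent entity is replaced by `$GENE_AGENT#`, every
#' mention of the target by `$GENE_TARGET#`, and every other gene/protein
#' mention by `BLANK`; non-mention text is unchanged. Replacements are
#' applied right to left so stored offsets stay valid. Masking third-party
#' entities suppresses them without altering the sentence's lexical
#' structure, so the classifier sees exactly one pair in context.
#'
#' @param sentence One-row sentence tibble carrying mentions.
#' @param agent,target Distinct normalized ids present among the mentions.
#' @return The labelled sentence text.
#' @export
render_labelled_sentence <- function(sentence, agent, target) {
  if (identical(agent, target)) {
    stop("agent and target must be distinct entities", call. = FALSE)
  }
  men <- sentence$mentions[[1]]
  men <- men[men$type == "gene/protein", , drop = FALSE]
  if (!(agent %in% men$norm_id) || !(target %in% men$norm_id)) {
    stop("agent and target must both be mentioned in the sentence",
         call. = FALSE)
  }
  text <- sentence$text[[1]]
  men <- men[order(-men$start), , drop = FALSE]
  for (i in seq_len(nrow(men))) {
    tag <- if (men$norm_id[[i]] == agent) gene_agent_tag()
           else if (men$norm_id[[i]] == target) gene_target_tag()
           else blank_tag()
    text <- paste0(substr(text, 1, men$start[[i]]), tag,
                   substring(text, men$end[[i]] + 1))
  }
  text
}

#' Enumerate directed candidate pair instances for one sentence
#'
#' With `n` distinct gene/protein entities, emits exactly `n * (n - 1)`
#' instances, one per ordered pair (direction matters: a sentence with two
#' entities yields two candidate relationships). Emission order is by
#' first-mention offset of the agent, then of the target.
#'
#' @param sentence One-row sentence tibble carrying mentions (it must have
#'   survived the entity-count eliminator: >= 2 distinct entities).
#' @return An instance tibble with rendered `labelled_text`, unscored.
#' @export
enumerate_instances <- function(sentence) {
  ents <- distinct_entities_in_order(sentence$mentions[[1]])
  if (length(ents) < 2) {
    stop(sprintf("sentence '%s' has fewer than two distinct entities",
                 sentence$sentence_id[[1]]), call. = FALSE)
  }
  rows <- list()
  for (a in ents) {
    for (t in ents) {
      if (identical(a, t)) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        instance_id = paste(sentence$sentence_id[[1]], a, t, sep = "|"),
        sentence_id = sentence$sentence_id[[1]],
        pmid = sentence$pmid[[1]],
        text = sentence$text[[1]],
        agent = a, target = t,
        labelled_text = render_labelled_sentence(sentence, a, t),
        score = NA_real_, label = NA_integer_)
    }
  }
  do.call(rbind, rows)
}

#' Enumerate instances for every sentence in a corpus
#'
#' @param sentences Sentence-corpus tibble (each row with >= 2 distinct
#'   entities).
#' @return Combined instance tibble.
#' @export
enumerate_instances_all <- function(sentences) {
  parts <- lapply(seq_len(nrow(sentences)),
                  function(i) enumerate_instances(sentences[i, ]))
  if (length(parts) == 0) return(empty_instances())
  do.call(rbind, parts)
}

#' Build the relation-classifier fine-tuning dataset
#'
#' Enumerates directed instances from a gold-annotated corpus and labels an
#' instance 1 iff its (agent, target) pair is among the sentence's gold
#' pairs, else 0. Sentences with fewer than two distinct entities contribute
#' no instances.
#'
#' @param corpus Sentence-corpus tibble whose rows carry `gold_pairs`
#'   (possibly empty, but not absent).
#' @return Labelled instance tibble; attribute `class_counts` holds the
#'   positive/negative tally.
#' @export
build_re_finetune_dataset <- function(corpus) {
  parts <- lapply(seq_len(nrow(corpus)), function(i) {
    gp <- corpus$gold_pairs[[i]]
    if (is.null(gp)) {
      stop(sprintf("sentence '%s' carries no gold annotation",
                   corpus$sentence_id[[i]]), call. = FALSE)
    }
    ents <- distinct_entities_in_order(corpus$mentions[[i]])
    if (length(ents) < 2) return(NULL)
    inst <- enumerate_instances(corpus[i, ])
    key <- paste(inst$agent, inst$target, sep = "\r")
    gold <- paste(gp$agent, gp$target, sep = "\r")
    inst$label <- as.integer(key %in% gold)
    inst
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  out <- if (length(parts) == 0) empty_instances() else do.call(rbind, parts)
  attr(out, "class_counts") <- c(positive = sum(out$label == 1L),
                                 negative = sum(out$label == 0L))
  out
}

#' Build the sentence-eliminator fine-tuning dataset
#'
#' A sentence dictating at least one regulatory relationship (non-empty gold
#' pairs) is labelled 1; the rest are labelled 0.
#'
#' @param corpus Sentence-corpus tibble with `gold_pairs`.
#' @return Tibble with columns `sentence_id`, `text`, `label`.
#' @export
build_elim1_finetune_dataset <- function(corpus) {
  if (nrow(corpus) == 0) {
    return(tibble::tibble(sentence_id = character(), text = character(),
                          label = integer()))
  }
  label <- vapply(corpus$gold_pairs, function(gp) {
    as.integer(!is.null(gp) && nrow(gp) > 0)
  }, integer(1))
  tibble::tibble(sentence_id = corpus$sentence_id, text = corpus$text,
                 label = label)
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Sentence-grouped k-fold cross-validation splits
#'
#' Folds are disjoint, exhaustive, and sized within one of each other. The
#' grouping unit is the unique sentence, so instances rendered from one
#' sentence never straddle train and test (which would leak the sentence's
#' wording across the split). Deterministic given `seed`.
#'
#' @param instances Labelled instance tibble.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of `k` elements, each `list(train =, test =)` integer row
#'   indices into `instances`.
#' @export
make_kfold_splits <- function(instances, k, seed) {
  stopifnot(k >= 2)
  ids <- unique(instances$sentence_id)
  if (k > length(ids)) {
    stop(sprintf("k = %d exceeds the %d unique sentences available", k,
                 length(ids)), call. = FALSE)
  }
  shuffled <- with_local_seed(seed, sample(ids))
  fold_of <- stats::setNames(rep(seq_len(k), length.out = length(shuffled)),
                             shuffled)
  lapply(seq_len(k), function(f) {
    test_ids <- names(fold_of)[fold_of == f]
    test <- which(instances$sentence_id %in% test_ids)
    list(train = setdiff(seq_len(nrow(instances)), test), test = test)
  })
}
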