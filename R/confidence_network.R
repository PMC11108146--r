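#' Confidence-scoring configuration
#'
#' @param K Non-negative balance factor weighting the prior-knowledge term
#'   `CF2` against the literature-evidence term `CF1`. Profiles used in
#'   practice: 1 when prior and literature evidence sit on comparable
#'   scales, 2 when literature vote sums run higher.
#' @param gamma Optional confidence threshold; relations with `CF < gamma`
#'   are treated as false positives. Select with [select_gamma_roc()] or set
#'   manually.
#' @param vote_cutoff Positive decision threshold applied to instance scores
#'   before they become votes.
#' @return An object of class `confidence_config`.
#' @export
confidence_config <- function(K = 1, gamma = NULL, vote_cutoff = 0.5) {
  stopifnot(K >= 0, is.null(gamma) || gamma >= 0,
            vote_cutoff >= 0, vote_cutoff <= 1)
  structure(list(K = K, gamma = gamma, vote_cutoff = vote_cutoff),
            class = "confidence_config")
}

#' Collapse refined positive instances into per-sentence votes
#'
#' Instances sharing (agent, target) and byte-identical sentence text are
#' averaged into a single vote: a relation stated twice in one sentence, or
#' in the same sentence reprinted in several abstracts, counts once with the
#' arithmetic mean of its classifier scores. Distinct sentences stating the
#' same relation contribute distinct votes.
#'
#' @param instances Refined, positively classified instance tibble.
#' @return A vote tibble with columns `agent`, `target`, `text`, `vote`, and
#'   list columns `pmids`, `sentence_ids` of supporting evidence.
#' @export
sentence_votes <- function(instances) {
  if (nrow(instances) == 0) {
    return(tibble::tibble(agent = character(), target = character(),
                          text = character(), vote = double(),
                          pmids = list(), sentence_ids = list()))
  }
  key <- paste(instances$agent, instances$target, instances$text, sep = "\r")
  idx <- split(seq_len(nrow(instances)), key)
  idx <- idx[order(vapply(idx, min, integer(1)))]  # first-appearance order
  rows <- lapply(idx, function(i) {
    tibble::tibble(agent = instances$agent[[i[1]]],
                   target = instances$target[[i[1]]],
                   text = instances$text[[i[1]]],
                   vote = mean(instances$score[i]),
                   pmids = list(unique(instances$pmid[i])),
                   sentence_ids = list(unique(instances$sentence_id[i])))
  })
  do.call(rbind, rows)
}

#' Prior-knowledge score for one directed pair in one database
#'
#' Returns 3 when (agent, target) is a curated relation in the database
#' (two entities plus a connecting arc already known); 1 when the agent is a
#' known controlling entity but the relation itself is unknown; 0 otherwise.
#' Names are normalized before lookup, and every relation's agent counts as
#' a regulator.
#'
#' @param agent,target Entity names.
#' @param db One database entry of a `prior_kb` (`list(name, regulators,
#'   relations)`).
#' @return 0, 1 or 3.
#' @export
prior_score <- function(agent, target, db) {
  a <- normalize_entity_name(agent)
  t <- normalize_entity_name(target)
  if (any(db$relations$agent == a & db$relations$target == t)) return(3)
  if (a %in% db$regulators || a %in% db$relations$agent) return(1)
  0
}

#' Confidence factor for one directed edge
#'
#' Computes `CF = CF1 + K * CF2` where `CF1` is the sum of the per-sentence
#' votes (each in [0,1], so `0 <= CF1 <= n`) and `CF2` is the sum of the
#' prior scores over the `M` curated databases (`CF2` in `{0, ..., 3M}`).
#'
#' @param agent,target Entity names.
#' @param votes Numeric vector of per-unique-sentence votes (non-empty).
#' @param kb A `prior_kb`.
#' @param config A `confidence_config` (supplies `K`).
#' @return One-row tibble with `agent`, `target`, `n`, `CF1`, `CF2`, `CF`.
#' @export
compute_cf <- function(agent, target, votes, kb = prior_kb(),
                       config = confidence_config()) {
  stopifnot(inherits(kb, "prior_kb"), inherits(config, "confidence_config"))
  if (length(votes) == 0) {
    stop("an edge must have at least one supporting sentence vote",
         call. = FALSE)
  }
  stopifnot(all(votes >= 0 & votes <= 1))
  cf1 <- sum(votes)
  cf2 <- sum(vapply(kb$databases, function(db) prior_score(agent, target, db),
                    numeric(1)))
  tibble::tibble(agent = agent, target = target, n = length(votes),
                 CF1 = cf1, CF2 = cf2, CF = cf1 + config$K * cf2)
}

#' Aggregate votes into confidence-scored directed edges
#'
#' @param votes Vote tibble from [sentence_votes()].
#' @param kb A `prior_kb`.
#' @param config A `confidence_config`.
#' @return Edge tibble with columns `agent`, `target`, `n`, `CF1`, `CF2`,
#'   `CF` and list columns `support_pmids`, `support_sentences`.
#' @export
aggregate_edges <- function(votes, kb = prior_kb(),
                            config = confidence_config()) {
  if (nrow(votes) == 0) {
    return(tibble::tibble(agent = character(), target = character(),
                          n = integer(), CF1 = double(), CF2 = double(),
                          CF = double(), support_pmids = list(),
                          support_sentences = list()))
  }
  key <- paste(votes$agent, votes$target, sep = "\r")
  idx <- split(seq_len(nrow(votes)), key)
  idx <- idx[order(vapply(idx, min, integer(1)))]
  rows <- lapply(idx, function(i) {
    e <- compute_cf(votes$agent[[i[1]]], votes$target[[i[1]]],
                    votes$vote[i], kb, config)
    e$support_pmids <- list(unique(unlist(votes$pmids[i])))
    e$support_sentences <- list(unique(unlist(votes$sentence_ids[i])))
    e
  })
  do.call(rbind, rows)
}

edge_key <- function(agent, target) {
  paste(normalize_entity_name(agent), normalize_entity_name(target),
        sep = "\r")
}

#' Select the confidence threshold by ROC analysis
#'
#' Sweeps every distinct CF value as a candidate threshold (predicted
#' positive: `CF >= gamma`), computes the true- and false-positive rates
#' against the gold relation set, and returns the threshold maximizing
#' Youden's J = TPR - FPR. Ties are broken toward the larger threshold
#' (fewer false positives).
#'
#' @param edges Scored edge tibble.
#' @param gold Data frame of true directed relations (`agent`, `target`).
#' @return The selected threshold gamma.
#' @export
select_gamma_roc <- function(edges, gold) {
  stopifnot(nrow(edges) > 0)
  if (is.null(gold) || nrow(gold) == 0) {
    stop("ROC threshold selection requires a non-empty gold relation set",
         call. = FALSE)
  }
  is_gold <- edge_key(edges$agent, edges$target) %in%
    edge_key(gold$agent, gold$target)
  if (all(is_gold) || !any(is_gold)) {
    stop("ROC is undefined when all or none of the edges are gold relations",
         call. = FALSE)
  }
  thresholds <- sort(unique(edges$CF))
  npos <- sum(is_gold)
  nneg <- sum(!is_gold)
  best_g <- NA_real_
  best_j <- -Inf
  for (g in thresholds) {
    pred <- edges$CF >= g
    j <- sum(pred & is_gold) / npos - sum(pred & !is_gold) / nneg
    if (j > best_j || (j == best_j && g > best_g)) {
      best_j <- j
      best_g <- g
    }
  }
  best_g
}

#' Filter edges by the confidence threshold
#'
#' Edges with `CF < gamma` are treated as false positives and dropped; an
#' edge with `CF` exactly equal to `gamma` is kept (the drop condition is
#' strict).
#'
#' @param edges Scored edge tibble.
#' @param gamma Threshold (>= 0).
#' @return The kept subset.
#' @export
filter_edges <- function(edges, gamma) {
  stopifnot(gamma >= 0)
  edges[edges$CF >= gamma, , drop = FALSE]
}

#' Export the confidence-weighted interaction network
#'
#' Writes the directed network with each edge's confidence factor as its
#' weight and each node's in-degree as a node attribute (the conventional
#' sizing attribute in network viewers).
#'
#' Formats: `"tsv"` — edge table with columns `agent`, `target`,
#' `n_sentences`, `CF1`, `CF2`, `CF`, `support_pmids` (semicolon-joined);
#' `"sif"` — `agent<TAB>regulates<TAB>target`; `"graphml"` — directed
#' GraphML with edge attribute `weight` and node attribute `in_degree`.
#'
#' @param edges Kept edge tibble.
#' @param format One of `"tsv"`, `"sif"`, `"graphml"`.
#' @param path Output file path.
#' @export
export_network <- function(edges, format = c("tsv", "sif", "graphml"),
                           path) {
  format <- match.arg(format)
  if (format == "tsv") {
    support <- if ("support_pmids" %in% names(edges)) {
      vapply(edges$support_pmids, paste, character(1), collapse = ";")
    } else {
      rep("", nrow(edges))
    }
    tab <- data.frame(agent = edges$agent, target = edges$target,
                      n_sentences = edges$n, CF1 = edges$CF1,
                      CF2 = edges$CF2, CF = edges$CF,
                      support_pmids = support)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "sif") {
    writeLines(if (nrow(edges) == 0) character(0) else
      paste(edges$agent, "regulates", edges$target, sep = "\t"), path)
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$agent, to = edges$target),
      directed = TRUE)
    igraph::E(g)$weight <- edges$CF
    igraph::V(g)$in_degree <- igraph::degree(g, mode = "in")
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
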