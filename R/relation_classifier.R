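#' Rule-based relation scorer
#'
#' Deterministic stand-in for a fine-tuned relation classifier, scoring an
#' anonymized labelled sentence in [0,1]:
#'
#' * `score_forward` (default 0.9) when an interaction trigger stem occurs
#'   between or adjacent to the tag pair, the agent tag precedes the target
#'   tag, and no other entity token (`BLANK` or a second tag) lies between
#'   the two tags;
#' * `score_reverse` (default 0.6) likewise but with the target tag first —
#'   the asymmetry keeps direction information alive through the pipeline;
#' * `score_none` (default 0.1) otherwise.
#'
#' The examined window (the span between the two tags plus `adjacency`
#' characters on either side) must contain no entity token other than the
#' pair itself (`BLANK` or a further tag occurrence): a trigger verb next to
#' a third entity most plausibly binds that entity, not the pair under
#' consideration.
#'
#' @param triggers Trigger stems (see [default_trigger_stems()]).
#' @param score_forward,score_reverse,score_none Configurable score values.
#' @param adjacency Adjacency window width in characters.
#' @return An object of class `relation_scorer` with a vectorized
#'   `score(labelled_texts)` element and a configuration digest.
#' @export
rule_relation_scorer <- function(triggers = default_trigger_stems(),
                                 score_forward = 0.9, score_reverse = 0.6,
                                 score_none = 0.1, adjacency = 30L) {
  stopifnot(all(c(score_forward, score_reverse, score_none) >= 0),
            all(c(score_forward, score_reverse, score_none) <= 1))
  trig_pat <- paste0("\\b(", paste(triggers, collapse = "|"), ")")
  cfg <- list(triggers = triggers, score_forward = score_forward,
              score_reverse = score_reverse, score_none = score_none,
              adjacency = as.integer(adjacency))
  score_one <- function(text) {
    a <- regexpr(gene_agent_tag(), text, fixed = TRUE)
    t <- regexpr(gene_target_tag(), text, fixed = TRUE)
    if (a == -1 || t == -1) {
      stop("labelled text lacks an agent or target tag", call. = FALSE)
    }
    second_start <- max(a, t)
    window <- substr(text, max(1L, min(a, t) - cfg$adjacency),
                     min(nchar(text),
                         second_start + attr(if (a < t) t else a,
                                             "match.length") - 1L +
                           cfg$adjacency))
    probe <- sub(gene_agent_tag(), " ", window, fixed = TRUE)
    probe <- sub(gene_target_tag(), " ", probe, fixed = TRUE)
    clean <- !grepl(blank_tag(), probe, fixed = TRUE) &&
      !grepl(gene_agent_tag(), probe, fixed = TRUE) &&
      !grepl(gene_target_tag(), probe, fixed = TRUE)
    if (clean && grepl(trig_pat, probe, ignore.case = TRUE, perl = TRUE)) {
      if (a < t) cfg$score_forward else cfg$score_reverse
    } else {
      cfg$score_none
    }
  }
  structure(list(
    name = "rule-stub",
    config = cfg,
    config_digest = paste(deparse(cfg), collapse = ""),
    score = function(labelled_texts) {
      vapply(labelled_texts, score_one, numeric(1), USE.NAMES = FALSE)
    }), class = "relation_scorer")
}

#' Score a single rendered instance with the rule scorer
#'
#' @param instance One-row instance tibble (or a list with `labelled_text`).
#' @param scorer A `relation_scorer`; defaults to the rule stub.
#' @return Score in [0,1].
#' @export
stub_score <- function(instance, scorer = rule_relation_scorer()) {
  scorer$score(instance$labelled_text[[1]])
}

#' Add a noise layer to a relation scorer
#'
#' Wraps a base scorer so each score is perturbed multiplicatively by a
#' uniform relative error in `[-noise, +noise]`, clipped to [0,1].
#' Deterministic given `seed`; used to probe ranking robustness of the
#' confidence factor.
#'
#' @param base A `relation_scorer`.
#' @param noise Relative noise amplitude in [0,1].
#' @param seed Integer seed.
#' @return A `relation_scorer`.
#' @export
noisy_relation_scorer <- function(base, noise = 0.2, seed = 1L) {
  stopifnot(inherits(base, "relation_scorer"), noise >= 0, noise <= 1)
  structure(list(
    name = paste0(base$name, "+noise"),
    config = c(base$config, list(noise = noise, seed = seed)),
    score = function(labelled_texts) {
      v <- base$score(labelled_texts)
      eps <- with_local_seed(seed, stats::runif(length(v), -noise, noise))
      pmin(1, pmax(0, v * (1 + eps)))
    }), class = "relation_scorer")
}

#' Score a set of instances
#'
#' Applies the scorer to every rendered instance, preserving input order. A
#' scorer failure leaves the instance unscored (`NA`) with a warning and the
#' run continues.
#'
#' @param instances Instance tibble with `labelled_text`.
#' @param scorer A `relation_scorer`.
#' @return The instances with `score` filled in.
#' @export
score_instances <- function(instances, scorer) {
  stopifnot(inherits(scorer, "relation_scorer"))
  if (nrow(instances) == 0) return(instances)
  scores <- tryCatch(scorer$score(instances$labelled_text),
                     error = function(e) e)
  if (inherits(scores, "error")) {
    # retry row-wise so one bad instance does not void the batch
    scores <- rep(NA_real_, nrow(instances))
    for (i in seq_len(nrow(instances))) {
      scores[i] <- tryCatch(scorer$score(instances$labelled_text[[i]]),
                            error = function(e) {
                              warning(sprintf(
                                "scorer failed on instance '%s': %s",
                                instances$instance_id[[i]],
                                conditionMessage(e)), call. = FALSE)
                              NA_real_
                            })
    }
  }
  ok <- !is.na(scores)
  stopifnot(all(scores[ok] >= 0 & scores[ok] <= 1))
  instances$score <- scores
  instances
}

#' Keep positively classified instances
#'
#' @param scored Scored instance tibble (no `NA` scores).
#' @param cutoff Positive decision threshold in [0,1]; an instance is
#'   positive iff `score >= cutoff`.
#' @return The positive subset.
#' @export
classify <- function(scored, cutoff = 0.5) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  if (nrow(scored) > 0 && anyNA(scored$score)) {
    stop("classify() requires every instance to carry a score", call. = FALSE)
  }
  scored[scored$score >= cutoff, , drop = FALSE]
}

#' Fine-tuning hyperparameter configuration
#'
#' Defaults follow the published configuration for the transformer relation
#' classifier: token length 256 or 512 depending on average sentence length,
#' batch size 8, 10 or 20 epochs depending on dataset size, learning rate
#' 2e-5 with warmup proportion 0.1 and weight decay 0.01.
#'
#' @param base_model Pretrained model identifier.
#' @param token_max_length 256 or 512.
#' @param optimizer Optimizer name.
#' @param batch_size,epochs,learning_rate,warmup_proportion,weight_decay
#'   Numeric training controls (all positive).
#' @return An object of class `train_config`.
#' @export
train_config <- function(base_model = "biobert_v1.1_pubmed",
                         token_max_length = 256L, optimizer = "BertAdam",
                         batch_size = 8L, epochs = 10L,
                         learning_rate = 2e-5, warmup_proportion = 0.1,
                         weight_decay = 0.01) {
  stopifnot(token_max_length %in% c(256L, 512L),
            batch_size > 0, epochs > 0, learning_rate > 0,
            warmup_proportion > 0, weight_decay > 0)
  structure(list(base_model = base_model,
                 token_max_length = as.integer(token_max_length),
                 optimizer = optimizer, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 warmup_proportion = warmup_proportion,
                 weight_decay = weight_decay), class = "train_config")
}

#' Transformer fine-tuning adapter
#'
#' Trains a relation classifier from a labelled dataset and returns a
#' scorer honoring the `relation_scorer` contract. Model training runs
#' through an external deep-learning backend that is not a dependency of
#' this package; when no backend is registered the adapter raises an
#' explicit capability error rather than silently falling back to the rule
#' stub.
#'
#' @param train Labelled instance tibble (non-empty).
#' @param config A `train_config`.
#' @param backend Optional function `(train, config) -> relation_scorer`
#'   supplied by an integration layer.
#' @return A `relation_scorer`.
#' @export
finetune_adapter <- function(train, config = train_config(), backend = NULL) {
  stopifnot(inherits(config, "train_config"))
  if (nrow(train) == 0) {
    stop("fine-tuning requires a non-empty labelled dataset", call. = FALSE)
  }
  if (anyNA(train$label)) {
    stop("fine-tuning requires every instance to carry a label",
         call. = FALSE)
  }
  if (is.null(backend)) {
    stop(paste("no fine-tuning backend is available: supply `backend` from",
               "an integration layer with transformer support"),
         call. = FALSE)
  }
  scorer <- backend(train, config)
  stopifnot(inherits(scorer, "relation_scorer"))
  scorer
}
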