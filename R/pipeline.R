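#' Run the full extraction pipeline over a set of abstracts
#'
#' Chains the three stages: (1) pre-processing — optional organism filter,
#' sentence splitting, relevance eliminator, entity-count eliminator;
#' (2) relation extraction — directed pair enumeration with anonymized
#' labelling, scoring, positive classification; (3) post-processing —
#' entity-name refinement, per-sentence vote averaging, and
#' confidence-factor aggregation against the prior knowledge base.
#'
#' @param abstracts Abstract tibble (`pmid`, `title`, `abstract`).
#' @param ner A `ner_provider` (e.g. [lexicon_ner()]).
#' @param kb A `prior_kb` (empty by default: `CF == CF1`).
#' @param organism Optional organism name; when given, abstracts not
#'   mentioning any of its surface forms are dropped.
#' @param relevance A `relevance_scorer` for eliminator 1.
#' @param scorer A `relation_scorer` for stage 2.
#' @param refine A `refinement_config`; defaults to the bundled stoplist and
#'   English lexicon with `ner` as word-level provider.
#' @param config A `confidence_config` (`K`, vote cutoff, optional gamma).
#' @param elim1_cutoff Decision threshold for the relevance eliminator.
#' @return A list with `edges` (confidence-scored, gamma-filtered when
#'   `config$gamma` is set), `votes`, `positives` (refined positive
#'   instances), and `report` (per-stage counts).
#' @export
run_pipeline <- function(abstracts, ner, kb = prior_kb(), organism = NULL,
                         relevance = rule_relevance_scorer(),
                         scorer = rule_relation_scorer(),
                         refine = refinement_config(provider = ner),
                         config = confidence_config(),
                         elim1_cutoff = 0.5) {
  n_abstracts_in <- nrow(abstracts)
  if (!is.null(organism)) {
    abstracts <- filter_abstracts_by_organism(abstracts,
                                              organism_name_forms(organism))
  }
  sentences <- split_sentences_all(abstracts)
  e1 <- eliminate_nonregulatory(sentences, relevance, cutoff = elim1_cutoff)
  e2 <- eliminate_by_entity_count(e1$kept, ner)
  instances <- enumerate_instances_all(e2$kept)
  scored <- score_instances(instances, scorer)
  positives <- classify(scored, cutoff = config$vote_cutoff)
  refined <- suppressWarnings(refine_relations(positives, refine))
  votes <- sentence_votes(refined)
  edges <- aggregate_edges(votes, kb, config)
  if (!is.null(config$gamma)) edges <- filter_edges(edges, config$gamma)
  report <- tibble::tibble(
    stage = c("abstracts_in", "abstracts_kept", "sentences_total",
              "removed_eliminator1", "removed_eliminator2", "sentences_kept",
              "instances", "positive_instances", "refined_instances",
              "edges"),
    n = c(n_abstracts_in, nrow(abstracts), nrow(sentences),
          nrow(e1$removed), nrow(e2$removed), nrow(e2$kept),
          nrow(instances), nrow(positives), nrow(refined), nrow(edges)))
  list(edges = edges, votes = votes, positives = refined, report = report)
}

#' Precision and recall of an edge set against a gold network
#'
#' Directed comparison on normalized names.
#'
#' @param edges Edge tibble (`agent`, `target`).
#' @param gold Gold relation data frame (`agent`, `target`).
#' @return Named list with `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
edge_set_metrics <- function(edges, gold) {
  pred <- unique(edge_key(edges$agent, edges$target))
  truth <- unique(edge_key(gold$agent, gold$target))
  tp <- length(intersect(pred, truth))
  list(precision = if (length(pred) == 0) NA_real_ else tp / length(pred),
       recall = if (length(truth) == 0) NA_real_ else tp / length(truth),
       tp = tp, fp = length(pred) - tp, fn = length(truth) - tp)
}
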