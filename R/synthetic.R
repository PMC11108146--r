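#' Synthetic-corpus configuration
#'
#' Controls the hermetic corpus generator. Every noise knob maps onto one
#' pipeline stage so each stage has a dedicated falsifier: irrelevant
#' sentences exercise the relevance eliminator, single-entity sentences the
#' entity-count eliminator, decoy entities the BLANK masking, multi-word
#' phrases the refinement step, and duplicated sentences the unique-sentence
#' vote averaging.
#'
#' @param seed Integer seed; the same seed yields identical corpora.
#' @param n_genes Number of genes in the synthetic genome.
#' @param n_true_relations Number of planted directed relations (at most
#'   `n_genes * (n_genes - 1)`).
#' @param n_abstracts Number of abstracts.
#' @param sentences_per_abstract Integer range `c(lo, hi)`.
#' @param p_irrelevant_sentence Fraction of sentences with no extractable
#'   relation (split between trigger-free and single-entity sentences).
#' @param p_decoy_entity Probability a relation sentence carries a third,
#'   uninvolved gene.
#' @param p_multiword_phrase Probability an endpoint is rendered as a
#'   descriptive multi-word phrase (e.g. "xyzA suppressor protein").
#' @param duplicate_sentence_rate Fraction of relation sentences reprinted
#'   verbatim in another abstract.
#' @param prior_coverage Fraction of planted relations present in the prior
#'   knowledge base.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 42L, n_genes = 30L, n_true_relations = 40L,
                       n_abstracts = 50L, sentences_per_abstract = c(6L, 8L),
                       p_irrelevant_sentence = 0.15, p_decoy_entity = 0.25,
                       p_multiword_phrase = 0.2,
                       duplicate_sentence_rate = 0.05,
                       prior_coverage = 0.5) {
  probs <- c(p_irrelevant_sentence, p_decoy_entity, p_multiword_phrase,
             duplicate_sentence_rate, prior_coverage)
  stopifnot(all(probs >= 0 & probs <= 1), n_genes > 0, n_true_relations > 0,
            n_abstracts > 0, length(sentences_per_abstract) == 2,
            sentences_per_abstract[1] >= 1,
            sentences_per_abstract[2] >= sentences_per_abstract[1])
  if (n_true_relations > n_genes * (n_genes - 1)) {
    stop("n_true_relations exceeds the number of ordered gene pairs",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_true_relations = as.integer(n_true_relations),
                 n_abstracts = as.integer(n_abstracts),
                 sentences_per_abstract = as.integer(sentences_per_abstract),
                 p_irrelevant_sentence = p_irrelevant_sentence,
                 p_decoy_entity = p_decoy_entity,
                 p_multiword_phrase = p_multiword_phrase,
                 duplicate_sentence_rate = duplicate_sentence_rate,
                 prior_coverage = prior_coverage), class = "sim_config")
}

#' Bundled relation sentence templates
#'
#' Templates are data, not code, so new sentence shapes can be added without
#' touching generator logic. Placeholders: `{agent}`, `{verb}`, `{target}`,
#' `{context}`, `{serial}`.
#'
#' @return Character vector of templates.
#' @export
default_sentence_templates <- function() {
  tpl <- readLines(system.file("extdata", "sentence_templates.txt",
                               package = "litgrn", mustWork = TRUE),
                   encoding = "UTF-8", warn = FALSE)
  tpl <- trimws(sub("#.*$", "", tpl))
  tpl[nzchar(tpl)]
}

synthetic_gene_names <- function(n) {
  names <- character(0)
  trig <- paste0("(", paste(default_trigger_stems(), collapse = "|"), ")")
  while (length(names) < n) {
    cand <- paste0(paste(sample(letters, 3, replace = TRUE), collapse = ""),
                   sample(LETTERS, 1))
    if (!grepl(trig, cand, ignore.case = TRUE) && !(cand %in% names)) {
      names <- c(names, cand)
    }
  }
  names
}

fill_template <- function(tpl, values) {
  for (k in names(values)) {
    tpl <- gsub(paste0("{", k, "}"), values[[k]], tpl, fixed = TRUE)
  }
  tpl
}

#' Generate a synthetic literature corpus
#'
#' Builds abstracts whose relation sentences instantiate trigger-verb
#' templates closed under the rule-based scorer's trigger list, so the
#' gold-oracle stub pipeline can recover every planted relation. Irrelevant
#' sentences either lack a trigger or carry a single entity; multi-word
#' phrase entities are refinable back to their bare names by the default
#' refinement configuration. Deterministic given `config$seed`.
#'
#' @param config A `sim_config`.
#' @return `list(abstracts =, sentences =, lexicon =, network =, config =)`:
#'   the abstract tibble, the gold standoff sentence corpus (mentions and
#'   gold pairs included), the gene lexicon, and the planted directed
#'   network (bare gene names).
#' @export
generate_corpus <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    genes <- synthetic_gene_names(config$n_genes)
    pairs <- expand.grid(agent = genes, target = genes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$agent != pairs$target, , drop = FALSE]
    network <- pairs[sample(nrow(pairs), config$n_true_relations), ,
                     drop = FALSE]
    rownames(network) <- NULL
    network <- tibble::as_tibble(network)

    counts <- sample(seq(config$sentences_per_abstract[1],
                         config$sentences_per_abstract[2]),
                     config$n_abstracts, replace = TRUE)
    total <- sum(counts)
    n_irr <- round(config$p_irrelevant_sentence * total)
    n_dup <- round(config$duplicate_sentence_rate * (total - n_irr))
    n_rel <- total - n_irr - n_dup
    if (n_rel < config$n_true_relations) {
      warning("fewer relation sentences than planted relations; some relations will be unexpressed",
              call. = FALSE)
    }
    rel_of_slot <- rep(sample(config$n_true_relations), length.out = n_rel)

    templates <- default_sentence_templates()
    verbs <- c("activates", "represses", "induces", "regulates")
    contexts <- c("stationary phase", "sporulation", "heat shock",
                  "stress response", "biofilm formation",
                  "exponential growth")
    phrase_suffixes <- c("suppressor protein", "gene product")
    phrases <- character(0)  # multi-word surfaces used, for the lexicon

    render_endpoint <- function(gene) {
      if (stats::runif(1) < config$p_multiword_phrase) {
        ph <- paste(gene, sample(phrase_suffixes, 1))
        phrases <<- unique(c(phrases, ph))
        ph
      } else {
        gene
      }
    }

    make_relation_sentence <- function(rel_idx, serial) {
      a <- network$agent[[rel_idx]]
      t <- network$target[[rel_idx]]
      text <- fill_template(sample(templates, 1),
                            list(agent = render_endpoint(a),
                                 verb = sample(verbs, 1),
                                 target = render_endpoint(t),
                                 context = sample(contexts, 1),
                                 serial = serial))
      if (stats::runif(1) < config$p_decoy_entity) {
        decoy <- sample(setdiff(genes, c(a, t)), 1)
        text <- sub("\\.$", paste0(", independently of ", decoy, "."), text)
      }
      list(text = text, rel = rel_idx)
    }

    make_irrelevant_sentence <- function(serial) {
      if (serial %% 2 == 0) {
        list(text = sprintf(
          "Samples were incubated overnight and counted in replicate %d.",
          serial), rel = NA_integer_)
      } else {
        list(text = sprintf("%s expression was measured in assay %d.",
                            sample(genes, 1), serial), rel = NA_integer_)
      }
    }

    slots <- vector("list", total)
    for (i in seq_len(n_rel)) {
      slots[[i]] <- make_relation_sentence(rel_of_slot[[i]], i)
    }
    for (i in seq_len(n_irr)) {
      slots[[n_rel + i]] <- make_irrelevant_sentence(n_rel + i)
    }
    if (n_dup > 0) {
      src <- sample(n_rel, n_dup, replace = n_dup > n_rel)
      for (i in seq_len(n_dup)) slots[[n_rel + n_irr + i]] <- slots[[src[i]]]
    }
    slots <- slots[sample(total)]

    lexicon <- tibble::tibble(surface = c(genes, phrases),
                              norm_id = c(genes, phrases))
    provider <- lexicon_ner(lexicon)

    pmids <- sprintf("SYN%04d", seq_len(config$n_abstracts))
    offsets <- c(0L, cumsum(counts))
    abs_rows <- vector("list", config$n_abstracts)
    sent_rows <- vector("list", total)
    k <- 0L
    for (i in seq_len(config$n_abstracts)) {
      mine <- slots[(offsets[i] + 1):offsets[i + 1]]
      texts <- vapply(mine, `[[`, character(1), "text")
      abs_rows[[i]] <- tibble::tibble(
        pmid = pmids[[i]],
        title = sprintf("Transcriptional regulation study %d in Bacillus subtilis", i),
        abstract = paste(texts, collapse = " "))
      for (j in seq_along(mine)) {
        k <- k + 1L
        men <- provider$annotate(texts[[j]])
        gp <- empty_pairs()
        if (!is.na(mine[[j]]$rel)) {
          a <- network$agent[[mine[[j]]$rel]]
          t <- network$target[[mine[[j]]$rel]]
          # gold pairs name the mention norm ids (phrase form when rendered
          # multi-word), keeping the standoff invariant intact
          ids <- men$norm_id
          a_id <- ids[ids == a | startsWith(ids, paste0(a, " "))][1]
          t_id <- ids[ids == t | startsWith(ids, paste0(t, " "))][1]
          gp <- tibble::tibble(agent = a_id, target = t_id)
        }
        sent_rows[[k]] <- new_sentence_corpus(
          sentence_id = sprintf("%s#%d", pmids[[i]], j),
          pmid = pmids[[i]], text = texts[[j]],
          mentions = list(men), gold_pairs = list(gp))
      }
    }
    list(abstracts = do.call(rbind, abs_rows),
         sentences = do.call(rbind, sent_rows),
         lexicon = lexicon, network = network, config = config)
  })
}

#' Generate a prior-knowledge base from a planted network
#'
#' A `prior_coverage` fraction of the planted relations (with their agents
#' as regulators) forms each curated database; databases are identical in
#' content, so the prior term scales with their number. Optionally writes
#' the two-table TSV layout.
#'
#' @param network Planted directed network (`agent`, `target`).
#' @param config A `sim_config` (supplies `prior_coverage` and `seed`).
#' @param n_databases Number of curated databases `M`.
#' @param dir Optional directory in which to write `regulators.tsv` and
#'   `relations.tsv`.
#' @return A `prior_kb`.
#' @export
generate_prior_kb <- function(network, config = sim_config(),
                              n_databases = 1L, dir = NULL) {
  stopifnot(nrow(network) > 0, n_databases >= 0)
  covered <- with_local_seed(config$seed + 1L, {
    n_cov <- round(config$prior_coverage * nrow(network))
    network[sample(nrow(network), n_cov), , drop = FALSE]
  })
  dbs <- lapply(seq_len(n_databases), function(i) {
    list(name = sprintf("db%d", i),
         regulators = unique(covered$agent),
         relations = covered)
  })
  kb <- prior_kb(dbs)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_prior_knowledge(kb, file.path(dir, "regulators.tsv"),
                          file.path(dir, "relations.tsv"))
  }
  kb
}
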