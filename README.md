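# litgrn — literature-derived gene regulatory networks

litgrn extracts **directed gene/protein regulatory interactions** from
publication abstracts and assembles them into a confidence-weighted network.
It is written for systems biologists who need machine-curated prior
knowledge — e.g. to seed gene-regulatory-network inference or to triage
literature for manual curation — and for text-mining developers who need a
hermetic, fully testable harness around model-backed relation extraction.

The pipeline has three stages:

1. **Pre-processing** — organism filtering, abbreviation-aware sentence
   splitting, and two sentence eliminators (no regulatory context; fewer
   than two distinct gene/protein entities).
2. **Relation extraction** — every ordered pair of distinct entities in a
   sentence ($n$ entities → $n(n-1)$ directed candidates) is rendered as an
   anonymized labelled sentence (`$GENE_AGENT#`, `$GENE_TARGET#`, third
   parties masked as `BLANK`) and scored in $[0,1]$ by a relation scorer.
3. **Post-processing** — entity-name refinement (phrase → bare gene name,
   incomplete relations dropped), per-unique-sentence vote averaging, and
   the confidence factor

   $$\mathrm{CF}_{e_ae_t} = \sum_{s=1}^{n}\bar v_s + K\sum_{T=1}^{M}P^{T}_{e_ae_t}
     = \mathrm{CF}_1 + K\,\mathrm{CF}_2,\qquad
     P_{e_ae_t}\in\{0,1,3\},$$

   where $P = 3$ for a relation already curated in database $T$, $1$ when
   only the agent is a known regulator, $0$ otherwise. Edges with
   $\mathrm{CF} < \gamma$ are discarded; $\gamma$ can be chosen by ROC
   analysis (maximum Youden's $J$) against a gold relation set.

The relevance scorer, relation scorer and named-entity recognizer are
pluggable contracts: deterministic rule/dictionary stubs are bundled (and
double as gold oracles in tests), while fine-tuned transformer classifiers
and external NER services can be slotted in unchanged. Dataset builders for
fine-tuning (directed-pair labelling, sentence-level labelling,
sentence-grouped k-fold splits) are included.

## Worked example

A synthetic corpus with a planted ground-truth network makes the whole
pipeline runnable offline:

```r
library(litgrn)

cfg <- sim_config(seed = 7L, n_genes = 12L, n_true_relations = 10L,
                  n_abstracts = 15L)
gen <- generate_corpus(cfg)            # abstracts, lexicon, planted network
kb  <- generate_prior_kb(gen$network, cfg)

res <- run_pipeline(gen$abstracts, lexicon_ner(gen$lexicon), kb = kb,
                    organism = "Bacillus subtilis")
res$report
#>                  stage   n
#> 1         abstracts_in  15
#> 2       abstracts_kept  15
#> 3      sentences_total 106
#> 4  removed_eliminator1   8
#> 5  removed_eliminator2   8
#> 6       sentences_kept  90
#> 7            instances 256
#> 8   positive_instances 180
#> 9    refined_instances 180
#> 10               edges  20

gamma <- select_gamma_roc(res$edges, gen$network)   # 7.2
kept  <- filter_edges(res$edges, gamma)
kept[1:5, c("agent", "target", "n", "CF1", "CF2", "CF")]
#>   agent target n CF1 CF2   CF
#> 1  jsgB   ozvH 9 8.1   1  9.1
#> 2  rofP   vudK 9 8.1   0  8.1
#> 3  ycmU   ozvH 8 7.2   3 10.2
#> 4  hqnD   xcxH 8 7.2   0  7.2
#> 5  xcxH   rofP 9 8.1   3 11.1

edge_set_metrics(kept, gen$network)[c("precision", "recall")]
#> $precision
#> [1] 1
#> $recall
#> [1] 1

export_network(kept, "graphml", "network.graphml")  # weight = CF, in-degree
```

Reading the edge table: `jsgB → ozvH` is supported by `n = 9` unique
sentences whose classifier votes sum to `CF1 = 8.1`; the prior database
knows `jsgB` as a regulator but not this relation (`CF2 = 1`), so with
`K = 1` the edge's confidence is `CF = 9.1`. Relations already curated in
the database get `CF2 = 3` per database. The ROC-selected threshold
`γ = 7.2` keeps exactly the ten planted relations (precision = recall = 1).

Real corpora enter through `read_abstracts()` (JSON Lines: `pmid`, `title`,
`abstract`), `read_standoff_corpus()` (sentence records with entity spans
and optional gold pairs), `read_prior_knowledge()` (two TSVs: regulators and
directed relations per database), and `read_gene_lexicon()`.

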