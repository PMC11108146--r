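---
title: "Methods: mining directed regulatory interactions from abstracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining directed regulatory interactions from abstracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litgrn)
```

## The problem and the model

Curated databases of transcriptional regulation (RegulonDB, Subtiwiki and
their kin) are built by experts reading papers. litgrn automates the core of
that reading task for publication abstracts: given a set of abstracts about
one organism, it produces a directed graph of gene/protein regulatory
relations, each weighted by a confidence factor that combines how often and
how strongly the literature asserts the relation with how well it agrees
with prior curated knowledge.

The pipeline has three stages.

**Stage 1 — pre-processing.** Abstracts are retrieved with a minimal query
(the organism name plus the keyword phrase
`r sQuote(default_keywords())`), filtered for an explicit organism mention
(full binomial or genus-initial abbreviation, matched case-insensitively in
title or abstract), and split into sentences. Two eliminators then discard
text that cannot yield a relation: eliminator 1 removes sentences without
regulatory context (a relevance classifier; the bundled rule stub fires on
interaction trigger stems such as *regulat-*, *repress-*, *activat-*,
*induc-*, *bind-*, *express-*, *transcrib-*), and eliminator 2 removes
sentences with fewer than two **distinct** gene/protein entities, since no
directed pair can exist otherwise. Both eliminators return exhaustive,
disjoint partitions, and per-stage counts are reported.

**Stage 2 — relation extraction.** For each surviving sentence with $n$
distinct entities, all $n(n-1)$ ordered (agent, target) pairs are
enumerated. Each pair is rendered as an anonymized labelled sentence: every
mention of the agent becomes `$GENE_AGENT#`, every mention of the target
becomes `$GENE_TARGET#`, and any third-party gene/protein mention becomes
`BLANK`. The masking suppresses uninvolved entities without altering the
sentence's lexical structure; substituting the original names back restores
the sentence exactly (a tested invariant). A relation scorer maps the
labelled text to $v_s \in [0,1]$; instances with $v_s \ge 0.5$ are positive.

**Stage 3 — post-processing.** Entity names are refined to bare gene names
(below), votes are aggregated per unique sentence, and each directed edge
$e_a e_t$ receives the confidence factor

$$\mathrm{CF}_{e_ae_t} \;=\; \underbrace{\sum_{s=1}^{n} \bar v_s}_{\mathrm{CF}_1}
\;+\; K \underbrace{\sum_{T=1}^{M} P_{e_ae_t}^{T}}_{\mathrm{CF}_2},
\qquad
P_{e_ae_t} = \begin{cases}
3 & e_ae_t \text{ is a known relation}\\
1 & e_a \text{ is a known regulator, } e_ae_t \text{ unknown}\\
0 & \text{otherwise,}
\end{cases}$$

where $n$ counts the *unique* sentences supporting the relation, $\bar v_s$
is the mean score when the identical sentence (or an in-sentence duplicate
of the pair) is seen more than once, $M$ is the number of curated databases,
and $K \ge 0$ balances literature against prior evidence. Edges with
$\mathrm{CF} < \gamma$ are discarded as false positives; an edge at exactly
$\gamma$ is kept. The value 3 for a known relation reflects two known
entities plus a known connecting arc, against 1 for a known controlling
entity alone.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| eliminator-1 cutoff | 0.5 | decision threshold on the relevance score in [0,1] |
| classification cutoff | 0.5 | threshold on $v_s$ for a positive instance |
| `K` | 1 | prior/literature balance (dimensionless); 2 suits corpora whose vote sums run higher |
| `gamma` | ROC-selected | CF acceptance threshold |
| stub scores | 0.9 / 0.6 / 0.1 | forward / reversed / no-trigger rule-scorer values |
| adjacency | 30 chars | how far beyond the tag pair a trigger may sit |

The upstream classifiers report soft scores without a published
binarization threshold, so both cutoffs default to the natural midpoint 0.5.
`gamma` is chosen by sweeping every observed CF value as a threshold and
maximizing Youden's $J = \mathrm{TPR} - \mathrm{FPR}$ against a gold
relation set, breaking ties toward the larger threshold because the
post-processing stage exists to remove false positives.

## Rule stubs versus fine-tuned models

The relevance scorer, relation scorer, and named-entity provider are
contracts. The bundled implementations are deterministic rules (trigger
stems; a case-insensitive, longest-match-first dictionary annotator with
probability 1), which keeps every run hermetic and makes the stubs usable as
gold oracles in tests. Model-backed implementations — a fine-tuned
transformer classifier (`finetune_adapter()` with the published recipe:
token length 256/512, batch 8, 10/20 epochs, learning rate 2e-5, warmup 0.1,
weight decay 0.01) and an external NER/NEN service — plug into the same
slots; training and live retrieval are deliberately outside the package's
test surface because they need GPUs and network access.

One scoring rule deserves its rationale. The stub scores 0.9 only when a
trigger lies between or adjacent to the tag pair **and** no other entity
token (`BLANK` or a further tag) falls inside the examined window. A trigger
verb flanked by a third entity most plausibly takes that entity as its
argument — in "BLANK induces $GENE\_AGENT\#$ …", the inducer is the masked
gene, not the agent under consideration — and without the exclusion every
decoy-bearing sentence would mint spurious high-scoring pairs. The reversed
configuration scores 0.6 rather than 0 so that direction information
survives to the confidence stage, where sentence counts and priors resolve
it.

## Entity-name refinement

Recognizers often return phrases ("Dnak suppressor protein") rather than
names. Refinement (1) returns single words unchanged, (2) strips stoplist
words (bundled list of frequent descriptors: *protein*, *gene*, *factor*,
*suppressor*, ...; applied first because it is far cheaper than entity
lookup), (3) looks the remaining words up one by one with the word-level
provider, and (4) if nothing is recognized, falls back on a misspelling
heuristic: a word absent from a bundled common-English lexicon — or
containing digits or internal capitals — is taken to be a gene/protein name.
"Dnak suppressor protein" → "Dnak"; "suppressor protein" → nothing, and the
relation is dropped as incomplete. When several words survive, the first in
original order is kept with a warning. Refinement is idempotent, and
enlarging the stoplist can only shrink the surviving relation set (both
property-tested).

## The synthetic corpus: what it emulates and what it does not

`generate_corpus()` builds a hermetic study corpus: a synthetic genome, a
planted directed network, and abstracts whose relation sentences instantiate
bundled templates with trigger verbs drawn from the stub scorer's list, so
the stub pipeline is closed over the generator's output. Each noise knob
falsifies one stage: trigger-free and single-entity sentences
(`p_irrelevant_sentence`) exercise the two eliminators, third-gene decoys
(`p_decoy_entity`) exercise BLANK masking, multi-word renderings such as
"xyzA suppressor protein" (`p_multiword_phrase`) exercise refinement,
and verbatim duplicate sentences (`duplicate_sentence_rate`) exercise
unique-sentence vote averaging. `prior_coverage` controls what fraction of
the planted network the prior database knows.

Default study conditions, fixed once: 30 genes, 40 planted relations, 50
abstracts of 6–8 sentences, 15% irrelevant sentences, 25% decoys, 20%
multi-word renderings, 5% duplicates, 50% prior coverage, one database,
$K = 1$. The sizing is deliberate: relation sentences are dealt round-robin,
so each planted relation is asserted in $c \approx 7$ unique sentences,
giving planted edges $\mathrm{CF} \ge 0.9c$ while the strongest distractor —
the reversal of a planted relation, scored 0.6 per sentence plus at most
$K \cdot 1$ of prior credit — stays below it ($0.3c > K + 0.6$ holds for
$c \ge 6$). Under these conditions the ROC-selected $\gamma$ separates the
planted network exactly (precision = recall = 1), and with 20%
multiplicative score noise planted edges still dominate by mean CF.

Passing these tests shows the machinery is sound end to end; it does **not**
show that the rule stubs approach the accuracy of fine-tuned models on real
prose. The generator targets pipeline semantics, not linguistic realism: no
anaphora, no passive constructions, no cross-sentence relations, no
ambiguous entity boundaries.

## Numerical and degenerate-input choices

* Sentence splitting is rule-based and abbreviation-aware (genus initials
  "E.", "B.", plus "cf.", "e.g.", "i.e.", "sp.", "spp.", "et al.", ...);
  a pretrained splitter can be swapped in through the same interface.
  Concatenating the output reconstructs the abstract.
* Offsets are 0-based half-open over the stored sentence text; mention
  surfaces must equal their slices, mentions must not overlap.
* Entity names are grouped across papers by case-folding, stripping
  surrounding punctuation, and collapsing whitespace.
* Duplicate pmids keep the first record with a warning; a failing NER call
  removes only that sentence (fail-closed); a failing scorer leaves the
  instance unscored with a warning, and classification refuses unscored
  input.
* k-fold splits group by sentence so renderings of one sentence never
  straddle train and test; fold sizes differ by at most one; splits are
  seeded.
* Unique-sentence identity is exact string equality; near-duplicate
  detection is out of scope.
* An edge needs at least one vote; ROC selection requires a mixed gold
  labelling (errors otherwise).

## Known limitations

Relations spanning sentence boundaries are invisible. Direction comes only
from the classifier's asymmetry and the prior term; no explicit
direction-flipping rule is applied when a known regulator appears on the
target side. The misspelling heuristic will call rare but valid English
words gene-like. The bundled stoplist and English lexicon are compact
stand-ins meant to be replaced for production corpora.

## Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates the default
study corpus, runs the full pipeline with and without score noise, and
writes the recovered-network metrics together with the pair-count and
prior-score reference quantities as JSON. The test suite
(`testthat::test_dir("tests/testthat")`) covers the same properties at
smaller sizes, with independent oracles (brute-force enumeration, explicit
Eq-substitution loops, an exhaustive threshold sweep, and pROC as an
external ROC cross-check).
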