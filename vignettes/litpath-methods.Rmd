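---
title: "Methods: from abstracts to an age-annotated regulatory pathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from abstracts to an age-annotated regulatory pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litpath)
library(dplyr)
```

litpath assembles a regulatory pathway from literature and asks, for each
gene in it, *how old is this gene?* The pipeline has two arms. The text arm
ranks a corpus of abstracts against a background set, tags gene names and
interaction verbs, classifies gene co-mentions into evidence classes, and
curates the strongest class into a typed, evidence-carrying graph serialized
as KGML. The sequence arm builds a homolog cluster per gene by
bidirectional-best-hit (BBH) expansion from curated seed proteins, and maps
the cluster's taxa onto a pinned taxonomy to find the most recent clade of
the root-to-human lineage that contains them all — the gene's last common
ancestor (LCA) — from which an ancient/recent label follows.

This vignette explains each model, its assumptions and tunable parameters,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## Abstract ranking

`fit_weights()` implements a smoothed log-odds (naive-Bayes presence) model
over document frequencies. For word $w$, with $n_t$ training and $n_b$
background documents, document frequencies $d_t(w)$, $d_b(w)$ and
pseudo-count $s$:

$$\mathrm{weight}(w) \;=\;
  \log\frac{d_t(w) + s}{n_t + 2s} \;-\; \log\frac{d_b(w) + s}{n_b + 2s}$$

An abstract's score is the sum of weights over its *distinct* vocabulary
words; repetition within an abstract does not count twice, matching the
document-frequency fit. The presence model was chosen over a count model
because it is the simplest realization of "discriminating words" and sits
behind a replaceable fitting interface; nothing downstream depends on the
choice.

Empirical p-values come from a resampling null: `null_size` pseudo-abstracts
are drawn word-wise from the background unigram distribution, with lengths
drawn from the background length distribution, and

$$p(a) = \frac{1 + \#\{\text{null scores} \ge \mathrm{score}(a)\}}{\text{null\_size} + 1}.$$

The $+1$ correction keeps $p \ge 1/(\text{null\_size}+1)$ and makes the
p-value valid rather than merely asymptotic. Defaults: `smoothing = 1`,
`null_size = 10000`, selection of the top `n_top = 1000` abstracts at
`p_threshold = 0.01` — the conventional working-corpus cut for this kind of
relevance ranking. Ties in score are broken by ascending PMID so rankings
are reproducible. Training abstracts are excluded from the ranked output,
since they were hand-picked rather than retrieved.

## Biointeraction extraction

Sentences are split by a rule: sentence-final punctuation followed by
whitespace and a capital or digit, with a protected-abbreviation list
("e.g.", "et al.", ...). The splitter is reversible — sentences plus their
separators reconstruct the input byte-for-byte — which makes offsets
trustworthy.

Gene tagging is dictionary matching: token-boundary anchored, longest match
wins, left to right. Synonyms of three characters or fewer match
case-sensitively (otherwise "LIF" would tag "life"); longer synonyms match
case-insensitively. Interaction words come from a packaged lexicon of ~60
verb forms with polarity (activation / repression / neutral); morphological
variants are listed explicitly rather than stemmed, and the lexicon is fully
user-replaceable.

Each ordered pair of distinct gene mentions (A's span strictly before B's)
in one sentence is classified:

* **type 1** — an interaction word lies strictly between A and B
  ("CDX2 downregulates NANOG"): the strongest evidence class, and the only
  class curated into the pathway by default;
* **type 2** — the sentence contains an interaction word, but not between
  the pair;
* **type 3** — co-mention in a sentence with no interaction word;
* **type 4** — co-mention at abstract level only, never inside a sentence.

Types 2–4 are deliberately weak-evidence classes; the hierarchy follows the
sentence/abstract co-occurrence ladder standard in co-mention mining, and
the "strictly between" reading of type 1 is the conservative interpretation
of "gene, word, gene, in that order". When several words lie between a
pair, the word nearest to A is attributed (deterministic single-word
attribution); for type 2 the first interaction word in sentence order is
attributed. Self-pairs (one symbol on both sides) are suppressed.

## Curation and KGML

Manual curation is replaced by declarative `curation_rules()`: accepted
types (default `{1}`), a polarity-to-subtype map (activation → activation,
repression → inhibition), word-level overrides for neutral verbs (binds →
binding/association, phosphorylates → phosphorylation), and symbol
allow/deny lists. Edge direction is textual order; duplicate assertions
merge and accumulate evidence PMIDs, so curation is idempotent and every
edge is traceable to the abstracts that support it.

`write_kgml()` emits KGML with integer entry ids assigned in lexicographic
symbol order, a deterministic grid layout for graphics coordinates, and two
lossless dialect extensions: evidence PMIDs in an extra
`subtype name="evidence"` child, and the ancestry annotation encoded in the
graphics fill color (lilac = ancient, green = recent, grey = unassigned)
with the fly-ortholog marker as a trailing `*` on the display label — the
conventions used in pathway figures of this kind. The writer produces bytes
directly so output is stable across platforms; `read_kgml()` inverts it
exactly, and `kgml_validate()` runs genuine libxml2 DTD validation against
the packaged KGML v0.7.2 DTD. Entries carry gene symbols rather than KEGG
Orthology ids so documents are self-contained (many literature-derived
genes have no KO entry).

```{r kgml-demo, eval = FALSE}
graph <- as_pathway_graph(litpath_demo_edges())
kgml <- write_kgml(graph)
kgml_validate(kgml)$valid
```

## Homolog clusters

`similarity()` is a deterministic local-alignment score (Smith–Waterman via
`Biostrings::pairwiseAlignment`, BLOSUM62, gap open 11 / extend 1 — the
classic protein-search parameterization). It is the pluggable oracle behind
the whole sequence arm; an external aligner could replace it behind the
same signature.

`seedlinkage_expand()` computes the BBH closure: starting from the seeds,
a candidate best hit in another taxon is recruited iff its best hit back
into the member's taxon is already a member, iterated to a fixed point.
This is the minimal scheme consistent with bidirectional-best-hit
clustering; promiscuity controls beyond a score floor are intentionally out
of scope. Ties are broken by ascending sequence id. `ko_union()` then adds
whole ortholog groups that contain a seed (one pass, after expansion), and
`verify_cluster()` re-checks every recruited member against the seeds,
discarding those below `min_verify_score` — seeds are never discarded.

The score floors are never hard-coded: `calibrate_thresholds()` takes a
labelled proteome and returns the midpoint between the lowest within-family
and the highest cross-family score. On the synthetic fixture the two
distributions are separated by an order of magnitude, so the midpoint is
robust; on real data the same function can be driven by any labelled
calibration set.

## Taxonomy and gene age

`load_taxonomy()` reads the NCBI taxdump dialect (`nodes.dmp`/`names.dmp`)
or an equivalent JSON, validates the tree (single root, no cycles, no
orphans) and pins it with a content checksum that is carried into every
ancestry result. The packaged mini-taxonomy intentionally retains
*Coelomata*, a clade dropped by modern NCBI taxonomies: gene-age bins are
meaningful only against the taxonomy version used to compute them, so the
taxonomy is version-pinned data, not a live lookup.

`lca_on_lineage()` returns the tip-most clade of the root-to-human lineage
that is an ancestor-or-self of every cluster taxon (a cluster taxid that is
itself a lineage node counts as subtended by itself). `classify_age()`
labels the LCA **ancient** when it lies strictly rootward of the reference
clade and **recent** otherwise — Euteleostomi itself is recent. The
reference defaults to Euteleostomi but is a parameter, because the
literature also uses Chordata as a cutoff for the same style of analysis;
results should state which cutoff they used. A Drosophila (taxid 7227)
ortholog is flagged separately; on any taxonomy in which the outgroup
branches rootward of the reference, the flag implies an ancient label.
Genes with no cluster (no curated seed product) yield no LCA row and
surface as "unassigned" grey nodes in the annotated pathway rather than
being silently dropped.

`bin_by_clade()` keeps zero-count clades so that origin histograms are
comparable across runs, and totals always equal the number of genes with
clusters.

## The synthetic-data generator

The generator is first-class, tested code; it defines the study conditions
under which all stages are validated.

**Corpora.** Abstracts are bags of sentences drawn from class word tables:
background abstracts from a uniform 200-word vocabulary, relevant abstracts
from the same vocabulary with 20 topic words at 5-fold enrichment — a clear
but imperfect separation that a ranker must resolve rather than trivially
threshold. Planted interactions are realized as sentences matching their
type's syntactic pattern exactly (type 1: gene A ... word ... gene B, one
sentence, that order) and recorded in a ground-truth table; filler words
come from the word tables so they can never collide with gene symbols or
lexicon verbs. Abstracts have 4–7 sentences of 8–14 words. The generator
does **not** emulate real language: no syntax, negation, anaphora,
species ambiguity or nested clauses. Passing extraction tests therefore
demonstrates correctness of the matching and classification rules, not
robustness to free text.

**Proteomes.** Each family starts from a uniform random amino-acid ancestor
(length 200 by default); the member for the i-th taxon derives from the
previous member by one round of i.i.d. substitution at `mutation_rate` per
site, so divergence accumulates along the taxon list. A family of size k
spans the first k taxa — the focal taxon plus its k−1 nearest relatives —
so family size maps to gene age the way real gene births do. Decoys are
i.i.d. random sequences at `decoy_rate` of the record set. At the default
`mutation_rate = 0.05` over six taxa, within-family identity stays above
~75% while decoy identity sits near the ~6% random expectation, so the true
partition is recoverable by construction; the tests verify that the
package's machinery actually recovers it. This is not a realistic model of
protein evolution (no indels, no rate heterogeneity, no domain structure) —
it is the minimal model under which BBH recovery is well-posed.

**Taxonomy.** The fixture spans the human lineage (cellular root,
Eukaryota, Metazoa, Eumetazoa, Coelomata, Chordata, Euteleostomi, Mammalia,
Eutheria, Homo sapiens) with mouse, zebrafish, fly, worm and yeast placed
as in older NCBI taxonomies. Taxon ids reuse the familiar NCBI numerals
purely as labels.

## Numerical choices and degenerate inputs

* All generators and the ranking null are driven by explicit integer seeds;
  identical seeds give byte-identical outputs, and the end-to-end pipeline
  is bitwise stable across runs.
* Score ties in ranking break by PMID; best-hit ties by sequence id;
  KGML entry ids by symbol order — every tie rule is total, so no output
  depends on input order.
* Empty inputs return empty, correctly-typed tibbles (empty corpus, empty
  interaction list, empty cluster list, empty histogram) rather than
  errors; invalid configurations raise classed errors naming the offending
  field.
* The `+1`-corrected empirical p-value can never be 0; the smallest
  attainable value is `1/(null_size+1)`, so `p_threshold` should be chosen
  with `null_size` in mind.

## Problem sizes

The shipped tests and examples run at desk scale, chosen so the full suite
completes in about a minute: corpora of 80–2010 abstracts (2000 for null
calibration, following the convention of ~2000 draws for an empirical
type-I-error check), proteomes of 5 families × 6 taxa plus decoys
(~33 sequences), and the 15-node taxonomy. All stages scale linearly in
corpus size; the similarity matrix is quadratic in proteome size and is the
first thing to replace (via the pluggable similarity oracle) for
proteome-scale work.

## Known limitations

* Dictionary tagging cannot resolve ambiguous symbols across species or
  distinguish genes from their products; there is no statistical NER,
  coreference or negation handling.
* Types 2–4 are heuristic evidence classes; only type 1 is curated by
  default, and even type-1 sentences can assert non-regulatory relations.
* The BBH closure has no profile-based (PSI-BLAST-style) sensitivity; remote
  homologs below the score floor are missed, which biases LCA estimates
  tipward — on real data the reported age is a lower bound on gene age.
* Gene-age bins depend on the pinned taxonomy version (Coelomata exists
  only in older taxonomies); the checksum attribute exists precisely so
  that results cannot be compared across unnoticed taxonomy changes.
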