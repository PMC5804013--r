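---
title: "Methods: literature-derived gene-disease association scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: literature-derived gene-disease association scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litgda)
```

## The model

`litgda` scores a gene-disease pair by how similar the literature *about*
the gene is to the literature *about* the disease, measured in a common
controlled vocabulary. The underlying assumption is distributional: genes
and diseases that are biologically linked are discussed with overlapping
MeSH keywords, even in articles that never mention both together. The
pipeline has five stages.

**1. Dictionary.** MeSH descriptors are parsed into a keyword-to-tree-position
table and restricted to the five categories most relevant to disease
biology (anatomy A, organisms B, diseases C, chemicals and drugs D,
psychiatry and psychology F). MeSH is polyhierarchical, so one keyword can
hold several tree positions; a single depth per keyword is needed for the
depth penalty below, and the package aggregates with the *maximum* (most
specific placement) by default. The deepest placement best reflects what an
author means when using a specific term; the `min` rule is provided for
users who prefer the most conservative reading, and the choice is exposed as
`depth_rule` everywhere it matters. Depth counts the category letter as
level 1, so a tree number with *s* dot-separated segments has depth *s* + 1.
This convention puts notoriously generic descriptors at small depths and
makes the penalty threshold of 5 meaningful.

**2. Document vectors.** A record (title, abstract, indexed MeSH terms) is
matched against the dictionary with case-insensitive, token-boundary,
longest-match-first, non-overlapping matching — the standard dictionary
convention, chosen because it is deterministic and has an obvious
brute-force oracle to test against. Three location vectors result: title
counts, per-sentence counts (the abstract is split by a rule-based splitter:
terminal punctuation, following whitespace, then an uppercase letter or
digit, with a small abbreviation guard), and a *binary* vector over the
indexed MeSH terms. They are combined as

$$raw_k = w_{title}\,t_k + \sum_i s_i\,a_{ik} + w_{mesh}\,m_k,\qquad
s_i = \begin{cases} w_{with} & \text{sentence } i \text{ mentions the entity}\\
w_{without} & \text{otherwise}\end{cases}$$

with defaults $w_{mesh}=3$, $w_{title}=2$, $w_{with}=2$, $w_{without}=1$.
The ordering encodes curation quality: indexed MeSH terms are deliberate
annotations, titles are strong signals, and a sentence that co-mentions the
target entity is worth as much as the title. Because of the co-mention
term, the representative vector is built per (document, entity) pair, not
per document. Setting all four weights to 1 (`uniform_weights()`)
reproduces the no-location-information ablation.

**3. Normalization.** Raw vectors are scaled to unit sum to remove
article-length bias. The default first applies $\log(1+v)$ and then scales
— damping the dominance of high-count keywords without the opposite bias of
plain unit-sum scaling, which over-weights documents containing few
keywords. Natural log is used; any base gives the same *ordering* but a
different normalized vector, so one base is fixed globally. Plain `sum1`
normalization is kept as an option for the normalization ablation. Note
that uniform scaling of the location weights cancels exactly under `sum1`
(degree-1 homogeneity of the combination step); under `log` the transform
is deliberately non-linear in the raw counts, so only `sum1` carries that
invariance.

**4. Term weighting.** Corpus-level importance is
$TW_k = IDF_k \cdot PWK_k$ with $IDF_k = \sqrt{1/\sum w_k}$, where
$\sum w_k$ sums keyword $k$'s entries across all document vectors in scope,
and $PWK_k = 2^{T_k-5}$ for depth $T_k < 5$, else 1. The square-root
inverse frequency damps ubiquitous keywords; the depth penalty halves the
weight per level above depth 5, suppressing near-root terms that are rare
enough to carry high IDF yet too generic to indicate a specific
association. IDF is computed separately over the gene-assigned and the
disease-assigned document vectors by default (`idf_scope = "split"`) —
keyword importance genuinely differs between the two corpora — with a
pooled `joint` option. Sums are taken over *normalized* vectors, the
declared product of the vectorization stage. Keywords never observed in a
scope have no defined IDF there and contribute zero to that scope's
profiles.

**5. Scoring and evaluation.** An entity profile is the TW-scaled sum of
its documents' vectors; every gene-disease pair is scored with cosine
similarity (non-negative inputs, hence scores in [0, 1]), computed as one
sparse matrix cross-product. Pairs where either profile is empty are kept
with score 0 and a `degenerate` flag rather than dropped, so precision and
recall denominators cover the full lexicon cross-product; users can filter
on the flag. Precision $P(x)$ and recall $R(x)$ use an *inclusive*
threshold ($\cos \ge x$); ties at the threshold are included; precision at
an empty denominator is reported as missing (`NA`), never 0 or 1, because
the ratio is undefined there. The sweep is reported raw, without
interpolation.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `w_mesh, w_title, w_abs_with, w_abs_without` | 3, 2, 2, 1 | location weights (unitless multipliers) |
| `norm_method` | `"log"` | document-vector normalization |
| `depth_rule` | `"max"` | multi-position keyword depth aggregation |
| `use_pwk` | `TRUE` | apply the depth penalty in TW |
| `idf_scope` | `"split"` | IDF over gene/disease corpora separately or pooled |
| `thresholds` | 0–1 step 0.01 | PR sweep grid |
| bin edges | 0, .01, .02, .05, .1, .2, .5, 1 | score-distribution bins, dense near 0 |

## The synthetic generator

`generate_study()` builds a fully controlled benchmark: a complete b-ary
toy MeSH tree (default depth 6, branching 3, under the five kept
categories), one keyword signature per entity drawn *without replacement*
from nodes at depth ≥ 5, and `floor(overlap * signature_size)` shared
keywords between the two sides of each planted gold pair. Signatures are
drawn from deep nodes so the depth penalty cannot confound signal-recovery
experiments; shallow "confounder" keywords can be injected explicitly
(`n_confounders`, `confounder_depth`) to exercise the penalty ablation, and
`abstract_signal = FALSE` restricts signal to titles and MeSH terms to
exercise the location-weight ablation. Each document carries its entity's
name (a synthetic token guaranteed absent from the keyword vocabulary, so
entity matching and keyword matching never collide) in the title, mixes
signature keywords with uniform off-signature noise (`noise_rate`) in the
sentences, mentions the entity per sentence with probability
`co_mention_prob`, and lists three signature keywords as indexed MeSH
terms. Defaults (50 genes, 20 diseases, 30 known pairs, signature size 10,
overlap 0.8, noise 0.1, 5 documents per entity, 4 sentences per document, 5
keyword slots per sentence, co-mention probability 0.8) are the package's
standard benchmark conditions: small enough to run in seconds, large
enough that recovery is a statistical rather than trivial property.
Sampling without replacement makes `overlap = 0` a clean null — signatures
are then fully disjoint and any known/unknown score difference is noise.

What the generator does *not* emulate: natural language (sentences are
templated token strings), synonymy and ambiguity of real gene symbols,
correlated document topics, citation structure, or the extreme sparsity of
real literature (where most genes have few disease-relevant articles).
Passing benchmarks therefore demonstrates correctness of the pipeline's
mechanics and its qualitative behavior under controlled signal, not
performance on real PubMed corpora.

## Numerical and degenerate-input choices

* Keyword and entity matching share one normalization (lowercase, collapse
  whitespace, tokenize on non-alphanumerics), so matching is deterministic
  across fields.
* `findInterval(..., rightmost.closed = TRUE)` realizes half-open bins with
  a closed last bin; a cosine of exactly 1 is counted.
* Top-k ranking breaks cosine ties by gene id then disease id, making
  reported top-k precision reproducible.
* Empty documents, empty lexicons, empty profiles and empty score ranges
  all produce well-defined outputs (empty tibbles, `degenerate` flags, or
  `NA`), never silent drops; empty gold standards error, since recall is
  undefined.
* All randomness flows through one seeded stream per generated study; the
  generator restores the caller's RNG state afterwards.

## Problem sizes

The test suite runs each oracle comparison on 50–100 randomized cases and
the end-to-end benchmarks at the standard conditions above (1000 pairs per
run, ten runs across seeds for the recovery and null checks); the
acceptance script runs one benchmark and one null study per invocation.
These sizes keep a full check under a few minutes on a laptop while leaving
the statistical assertions comfortably powered.

## Known limitations

* Dictionary matching cannot resolve ambiguous surface forms (a gene symbol
  that is also an English word); real-corpus use needs curated lexicons.
* The depth penalty uses a single aggregated depth per keyword; a
  position-specific penalty would require deciding which tree position a
  mention refers to, which plain dictionary matching cannot do.
* IDF is undefined for keywords absent from a scope, so a keyword seen only
  in disease documents contributes nothing to gene profiles (and vice
  versa) even if it appears in a gene document later scored against it.
* The all-pairs cosine is dense in the number of entity pairs; at around
  10^3 x 10^3 entities the association table (10^6 rows) is the practical
  ceiling for interactive use.
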