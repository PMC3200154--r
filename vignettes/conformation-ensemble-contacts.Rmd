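---
title: "Consensus contact prediction from conformation ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus contact prediction from conformation ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactensemble)
```

## The idea

*De novo* structure prediction pipelines produce large pools of candidate 3D
models ("decoys") for a target protein. For hard, template-free targets no
single model is reliable, but different models frequently get different
*parts* of the fold right. A residue pair that sits in contact across many
independently generated conformations is therefore far more likely to be a
real contact than one supported by a single model. This package turns that
observation into a predictor:

1. **Extract** contacts from every model in the pool. Two residues are in
   contact when their representative atoms — the C&beta;, or the C&alpha;
   for glycine — are strictly closer than 8 &Aring;.
2. **Count** each contact across all models and **normalize** to a
   frequency in (0, 1]: the fraction of models containing the pair.
3. **Sort** by frequency, **filter** to the target domain and to the
   medium (sequence separation 12–23) and long (&ge; 24) ranges, and
   **select** the most frequent contacts — conventionally the top *L*/5,
   with *L* the domain length — as the prediction.

The frequency doubles as the prediction confidence and is what the CASP RR
output carries. Downstream, the same machinery supports three analyses:
scoring predictions against a native structure, ranking the models of the
pool by how well each satisfies the consensus, and clustering the predicted
contacts to ask how the consensus is distributed across models.

## Definitions and parameters

All tunable constants live in `contact_params()`:

| parameter | default | meaning |
|---|---|---|
| `distance_threshold` | 8 &Aring; | contact cut-off, strict `<` |
| `medium_lo`–`medium_hi` | 12–23 | medium-range sequence separation (inclusive) |
| `long_lo` | 24 | minimum long-range separation |
| `delta` | 0 | &plusmn;&delta; tolerance when matching predictions to true contacts |
| `cluster_linkage` | 4 | residue distance joining two contacts into one cluster |
| `top_fraction` | 1/5 | prediction depth as a fraction of *L* |

The 8 &Aring; boundary is read as a strict inequality: a pair at exactly
8.000 &Aring; is not a contact. Separations below 12 are classified
`"short"`; they are retained in every `contact_map` (exclusion is a
filtering decision, not an extraction rule) but excluded from prediction
output by default, since medium and long range contacts are what matter
for fold assembly and what assessments score.

**Proximity between two contacts.** Several operations need "contact *a*
is within *d* residues of contact *b*": &delta;-tolerant evaluation,
cluster linkage, representative truth-filtering and coverage. All of them
share one metric, the Chebyshev distance on ordered index pairs,
`max(|a_i - b_i|, |a_j - b_j|)` — both endpoints must be within the
tolerance, and distance 0 is exact identity. A one-endpoint reading would
let a prediction claim credit for a true contact whose other end is
anywhere in the chain, which is clearly too generous; the both-endpoints
reading is the standard neighborhood interpretation and collapses to exact
matching at &delta; = 0.

**Normalization.** Frequencies divide raw counts by the number of models
in the ensemble, so `freq` is interpretable as "fraction of models
containing this contact". Dividing by the maximum count instead would
rescale all scores identically and leave every ranking in this package
unchanged; the per-model denominator is preferred for its interpretation.
Models that omit residues still count in the denominator for every pair —
there are no per-pair denominators.

**Determinism.** Every ordering in the package carries an explicit tie
rule: consensus entries tie-break by (i, j) ascending, top-k quality
filters and model rankings tie-break by model id ascending, cluster labels
follow the representative's (i, j). Identical inputs give byte-identical
RR output. Truncation to top *L* &times; fraction uses
`max(1, floor(L * fraction))`.

## Evaluation

Precision is the number of correct predictions over the number considered;
a prediction is correct at tolerance &delta; when some true contact of the
evaluated range lies within Chebyshev distance &delta;. Each prediction is
judged independently — one true contact may validate several nearby
predictions; no bipartite matching is attempted, which keeps the statistic
simple and monotone in &delta; (precision at &delta;+1 can never be lower
than at &delta;).

Recall is reported at &delta; = 0 only — the count of true contacts
recovered exactly, over the number of true contacts of that range —
because a &delta;-tolerant recall would have to decide how many
predictions a single true contact can absorb. Recall is computed over the
same truncated (top-*L*/5) prediction list as precision, and the report
header of the command-line tool says so. With an empty prediction list
precision is reported as 0 with an `undefined` flag rather than as NaN.
With `range = "both"`, medium and long predictions are pooled but each
prediction is matched only against truth of its own range class.

## Ranking models by contact satisfaction

Given medium and long prediction lists, each model is scored by four
fractions: medium predictions satisfied exactly, medium satisfied within 1
residue, and the same two for long — summed into a total in [0, 4]
(fractions rather than percentages; the scale is equivalent). Models are
ranked by total, descending. The quality of a ranking is measured as
*selection loss*: the quality score (e.g. GDT-TS) of the best model in the
pool minus that of the top-ranked model. The random baseline selects the
middlemost model by quality (lower median for even counts), so its loss is
best-minus-median.

Which contacts should the scoring lists contain? The design space is
genuinely open, and it matters. The lists follow the top-*L*-medium /
all-long shape, but both are restricted to the *recurrent* part of the
consensus: by default a contact must appear in at least a quarter of the
models (`consensus_prediction_sets(min_freq = 0.25)`; an absolute
`min_count` is available as an override). The rationale: the scheme
rewards models for realizing interactions the ensemble agrees on. On pools
whose members span a wide quality spectrum, contacts observed in only a
model or two are overwhelmingly noise — near-threshold pairs that recur
among the *worst* models — and scoring against them rewards reproducing
that noise; in our synthetic graded-noise experiments it decorrelates the
satisfaction total from true model quality entirely. A frequency floor,
unlike an absolute count, scales with the ensemble.

One consequence worth knowing: an exceptionally good model (or the native
itself) does not necessarily top a ranking computed against noisy
prediction lists, because recurrent near-threshold noise is satisfiable
only by models that share the ensemble's error statistics. Against
precision-dominated lists (for instance the planted truth of the synthetic
generator), the unperturbed reference does rank first — the package's
tests assert exactly that.

## Clustering predicted contacts

Long-range predictions are grouped by single linkage: two contacts within
`cluster_linkage = 4` residues (shared Chebyshev metric) join the same
cluster, and grouping is transitive, so a chain of pairwise-close contacts
forms one cluster even when its extremes are farther apart than the
linkage. Each cluster is represented by the member minimizing the L1
distance `|i - mean(i)| + |j - mean(j)|` to the cluster's mean endpoint
position (per-endpoint averaging; ties by (i, j) ascending).
Representatives are then truth-filtered — kept only within 4 residues of a
true contact — and each model's *coverage* is the number of retained
representatives matched within 4 residues by some contact of that model.
The coverage histogram is reported both as exact-count fractions and
cumulative ("at least k") fractions, since either convention is found in
practice and they answer different questions.

A low fraction of models covering *all* clusters, alongside healthy
per-cluster coverage, is the signature of genuine consolidation: the
consensus assembles an interaction pattern that no single model contains
in full.

## The synthetic-data generator

Real server pools and experimental structures cannot ship with a package,
so every claim above is exercised on synthetic ensembles with known ground
truth:

* `make_reference()` builds a deterministic fold: `helix_bundle` packs
  2–3 idealized helices (rise 1.5 &Aring;/residue, radius 2.3 &Aring;,
  100&deg;/residue, consecutive trace atoms &asymp; 3.8 &Aring; apart)
  side by side with &asymp; 9 &Aring; between axes, joined by short loops
  whose junction geometry keeps step lengths near 3.6 &Aring;. This
  guarantees inter-helix medium- and long-range contacts — the misfolded
  helical-bundle regime the method is designed to exploit. `random_coil`
  grows a clash-avoiding 3.8 &Aring; random walk. Every 7th residue is a
  glycine so the C&alpha; representative rule is exercised on disk.
* `make_ensemble()` adds i.i.d. Gaussian coordinate noise per model
  (default &sigma; = 1 &Aring;); a `corrupt_fraction` (default 20%) of
  models additionally rigid-shift the C-terminal ~35% of the chain by
  `corrupt_shift` (default 15 &Aring;), destroying that segment's
  long-range contacts — a desk-scale analogue of models that misplace a
  whole helical bundle. The optional `noise_range` draws each model's
  &sigma; uniformly from a range, emulating pools whose members span a
  quality spectrum; the ranking experiments use &sigma; &isin; [0.5, 2.5].
* Ground truth is the reference's own contact map, and each model's
  quality score is the fraction of true contacts it preserves — a
  contact-level stand-in for GDT-TS on [0, 1], used so that no
  superposition machinery is needed.

What the generator does *not* emulate: real decoys are not the native plus
isotropic noise — they have correlated, physically constrained errors,
alternative topologies and heterogeneous per-region quality; real pools
mix methods with shared templates (correlated errors across models); and
contact-preservation is only a proxy for GDT-TS. Passing tests therefore
demonstrate the correctness and internal coherence of the algorithms under
a controlled error model, not the accuracy levels to expect on real CASP
pools.

A quantitative caveat discovered with this generator: under coordinate
noise the distance between two atoms is biased upward (the noise adds in
quadrature), so planted contacts sitting just under the 8 &Aring; cut-off
survive 1 &Aring; noise only about half the time. Recurrence guarantees in
the tests are therefore asserted for contacts solidly inside the threshold
(reference distance < 6.5 &Aring;), and conversely spurious pairs just
*outside* 8 &Aring; recur in just under half the models — which is why a
frequency of 0.6 separates planted from spurious contacts in the frozen
fixtures.

## Problem sizes and numerical choices

The test-suite and acceptance experiments use 80-residue references, 50
model ensembles, 20 replicate seeds for the ranking comparison, and
brute-force oracle checks on up to 200 random models of &le; 100 residues
— sizes chosen so the full suite completes in about a minute while keeping
every statistic far from its small-sample regime. Coordinates are written
at PDB precision (3 decimals) and round-trip exactly at that precision; RR
scores are serialized with 6 decimals. Degenerate inputs are defined
errors, not silent results: models with fewer than 2 residues, empty
ensembles after filtering, rankings whose ids are missing from the quality
table, clustering of an empty prediction list.

## Known limitations

* Single chains only; insertion codes are rejected; mmCIF is out of scope.
* GDT-TS / TM-score computation is deliberately out of scope — quality
  scores are consumed from tables, never computed.
* The RR dialect is the classic 5-column one (`i j 0 8 p`); multi-bin
  distance extensions are not supported.
* Consensus frequency is not a calibrated probability; it is a ranking
  score.
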