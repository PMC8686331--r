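---
title: "Clustering single-base substitutions by long flanking context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering single-base substitutions by long flanking context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mutational processes leave sequence signatures: the base that mutates,
and the bases around it.  Classical signature analysis conditions on
one or two neighboring bases (the 96-class trinucleotide scheme),
because every additional flanking position multiplies the number of
categories by four — fifty bases of context on each side would give
6 x 4^100 categories, far beyond anything countable.  `mutblot` takes
the opposite route: it never enumerates context categories at all.
Each somatic single-base substitution (SBS), together with 50 bases of
5' and 3' flanking reference sequence, is embedded by a recurrent
network into an 8-dimensional feature vector, and the feature vectors
are clustered by a modified self-organizing map (SOM).  The resulting
clusters — "mutation blots" (MBs) — group substitutions that share
both their base change and the composition of their long flanks.
Downstream tools then relate per-patient MB composition to clinical
covariates and survival.

## Encoding

Bases are written as two-bit codes: A = (0,0), T = (0,1), C = (1,0),
G = (1,1), and N = (-1,-1) for unknown or padded positions.  A flank
base `b` becomes the 4-entry row `[b | b]`; the mutated position
becomes `[alt | ref]`, mutant code first.  A substitution with flanks
of length F is therefore an (2F + 1) x 4 matrix with the mutation row
in the middle.  The five-base example `CATTG > CACTG` (middle T
mutated to C, flanks "CA" and "TG") encodes as:

```{r}
library(mutblot)
encode_mutation_sequence(mutation_sequence("CA", "T", "C", "TG"))$matrix
#>      [,1] [,2] [,3] [,4]
#> [1,]    1    0    1    0
#> [2,]    0    0    0    0
#> [3,]    1    0    0    1
#> [4,]    0    1    0    1
#> [5,]    1    1    1    1
```

The mutant-first column order in the mutation row is what reproduces
row 3 above: (1,0) is the C code (the mutant), (0,1) the T code (the
reference).  The matrix is injective — the sequence is recoverable —
and this is property-tested.

For reporting (not for training), substitutions are collapsed to the
strand whose reference base is a pyrimidine, giving the six canonical
types C>A, C>G, C>T, T>A, T>C, T>G; the full flanked sequence is
reverse-complemented in that case, so the 5'→3' reading of the
opposite strand is preserved.  Training itself uses the raw
plus-strand alleles: no strand normalization is applied at ingestion,
and the collapse is available separately as `pyrimidine_collapse()`.

## The feature extractor

A recurrent reader gives the positions nearest its final step the
largest influence on its output.  To focus that recency on the
mutation, the encoded matrix is read twice — rows 1..site (5' flank
first) and rows n..site (3' flank first) — so the mutation row is the
final input of both reads.  One two-layer LSTM (64 units per layer,
weights shared between the two reading directions) processes both
reads; the two terminal hidden states are concatenated and a single
affine layer maps them to the 8-dimensional feature vector.

There is no deep-learning framework underneath: the forward pass, full
backpropagation through time, and the Adam optimizer (rate 0.001) are
implemented directly on BLAS-backed matrix operations.  The analytic
gradients are verified against numerical differentiation in the test
suite, and the documented recency property — a base adjacent to the
site perturbs the output more than a base 10 positions away — is
checked by Monte-Carlo over 100 random weight initializations.
Weights initialize uniformly in ±1/sqrt(64) with the forget-gate bias
shifted by +1 so gradients survive the ~50-step reads.

The extractor is trained by regression: `fit_to_labels()` performs two
full-batch Adam passes minimizing mean squared error against label
vectors — the SOM's feedback output, as described next.

## The modified self-organizing map

The competition layer holds 200 unit vectors living directly in the
8-dimensional feature space; there is no 2-D lattice, and all
neighborhood structure is defined by Euclidean distance.  For each
input feature vector x:

* `d_j(x)`: distance of x to every unit; the nearest unit is the
  winner `w_min`.
* `d_j(w_min)`: distance of every unit to the winner; sorted, the
  distance at rank `ceiling(quantile * n_units)` (winner itself is
  rank 1) is the threshold S.  The default quantile 0.2 places S at
  the distance of the unit at rank 40 of 200.
* Gaussian decay `D(w_j) = exp(-d_j(w_min)^2 / (2 pi sigma^2))`.
* Per-unit delta `Delta(w_j) = ± L · D(w_j) · (w_j - x)`, sign `+`
  within S and `-` beyond; units move by `-Delta(w_j)`, so units near
  the winner approach x while distant units recede.  L defaults to
  0.005.
* Input feedback `x(new) = x + sum_j Delta(w_j)`: the input moves
  opposite to the aggregate unit motion.  `x(new)` becomes the
  regression label for the extractor.

Unit movements are accumulated against the layer state frozen at batch
start and applied once per batch of 100 samples, which also makes the
update order-invariant within a batch (tested by permutation).  The
sign convention is the module's central subtlety: adding the printed
delta directly would move units *away* from x, so units are updated by
the negative delta while the feedback keeps the positive sum — this
combination satisfies both the attract/repel semantics and the
"opposite direction" feedback, and it is regression-tested against a
scalar brute-force oracle.  With the threshold opened wide (quantile
near 1) and feedback ignored, the update collapses to a classical
batch SOM step with a Gaussian neighborhood, which the tests verify
against an independent vanilla-SOM implementation.

### Sigma is in dispersion units

The neighborhood constant sigma has no natural absolute scale: a
freshly initialized extractor emits features whose spread depends on
the (arbitrary) weight initialization, and during training the spread
itself evolves.  Early experiments with an absolute sigma showed
degenerate behavior — when sigma dwarfs the feature spread every unit
counts as "local", the gated update turns purely attractive, and the
whole cloud collapses to a point.  `train_round()` therefore rescales
sigma once per round by the RMS dispersion of the first batch's
features, making the dynamics invariant to feature scale.  The default
sigma = 1.0 thus means "one initial dispersion unit".

## One training round

`train_round()` alternates, on a random batch of 100 encodings per
epoch: feature extraction, the SOM batch update, and two extractor
fitting passes toward x(new).  Two stopping safeguards operate on a
fixed monitor subsample (default 400 samples):

* **Stability.** Every 5 epochs the monitor features are provisionally
  split in two; when the adjusted Rand index between consecutive
  provisional splits reaches 0.98 twice in a row (and at least 15
  epochs have run), the classification is declared stable.  This
  criterion targets the object of interest — the classification —
  rather than raw feature movement, which keeps drifting long after
  the grouping has settled.
* **Clarity snapshot.** At each check the fraction of monitor-feature
  variance explained by the provisional split is recorded, and the
  weights and layer of the clearest snapshot are retained.  The final
  readout uses that snapshot, not necessarily the last epoch: on
  planted-truth data the split is essentially pure at its clarity peak
  (epoch 25–50) and then *degrades* under continued feedback, with
  misassignment rising from ~2% to ~35% by epoch 150.  Returning the
  clearest stable state is the package's operationalization of
  training "until a clear, stable classification", and it makes the
  epoch cap (default 60) uncritical.

### Readout

The final features of all samples are split into exactly two groups.
The default readout over-clusters the features into up to 12 k-means
subclusters and merges the subcluster centroids into two groups by
exhaustive minimization of the size-weighted within-group sum of
squares (at most 2^15 bipartitions — exact, deterministic).  Unlike a
plain 2-means cut, this boundary cannot slice through a tight feature
cluster.  Plain 2-means and a competition-unit-based readout remain
available as options.

A second safeguard, `anchor_readout` (on by default), addresses a
structural property of the dynamics: training deliberately collapses
fine context detail into the two emerging groups, so samples near the
boundary can end up on the wrong side even when their raw context is
unambiguous.  The anchored readout clusters the *raw encoded
sequences* into up to 24 subclusters (on planted data these are ~99%
class-pure) and snaps the binary assignment by majority vote within
each subcluster: the learned features decide which side a context
group belongs to, while the input-space geometry keeps each group
intact.  On ten-class planted data this step raised schedule-level
recovery from an adjusted Rand index of ~0.4 to ~0.8–0.9 without
touching the training dynamics.

## The splitting schedule

`run_schedule()` applies the binary round recursively: 3 rounds give
2^3 = 8 leaves, after which the 2 largest leaves are each split once
more, for 10 MB classes — the default configuration.  Every leaf gets
a fresh extractor and a fresh competition layer with seeds derived
deterministically from the master seed and the leaf's tree path, so
the full labeling is reproducible bit-for-bit.  Leaves smaller than
`min_leaf` (default 4) are left intact with a warning.  Final classes
are numbered MB 1, MB 2, ... by decreasing size, ties broken by tree
path.

## Downstream analyses

* `mb_composition()`: per-patient MB proportions (rows sum to 1);
  TCGA-style barcodes are collapsed to their 12-character patient
  prefix.
* `spectrum_summary()`: per-MB fractions of the six canonical
  substitution types and per-flank-position base fractions, after
  pyrimidine collapse.
* `cluster_patients()`: seeded K-means on the proportion rows.  The
  default K = 7; with `K = "auto"` the within-cluster sum of squares
  is scanned over k = 2..10 and the knee is chosen by maximum second
  difference — an explicit, reproducible form of the usual visual
  elbow reading.
* `group_compare()`: pooled-variance t test for numeric outcomes in
  two groups, one-way ANOVA beyond two, chi-square for categorical
  outcomes (R's default Yates correction for 2x2 tables); rows missing
  the outcome or group are removed per analysis and counted, and a
  group emptied by removal is an error rather than a silent drop.  No
  multiple-testing correction is applied by default, matching the raw
  p < 0.05 reporting convention of the analyses this reproduces;
  `p.adjust` can be applied by the caller.
* `logrank()`: log-rank test via `survival::survdiff`, validated in
  the tests against an explicit risk-set tabulation oracle to 1e-10.
  For per-gene survival, `mb_gene_groups()` groups patients by the MB
  class of their mutations in one gene; a patient whose mutations span
  several MBs enters every group by default (exclusive-assignment and
  drop modes are provided).

## The synthetic-data generator

The generator exists so the whole pipeline is testable end to end with
no downloads, and its defaults define the package's study conditions:

* `generate_reference()`: i.i.d. bases at GC 0.41 (human-like).
* `context_profile()`: per-class substitution type and favored flank
  bases.  The favored-base probability is `p_max` (default 0.85)
  immediately next to the site and decays exponentially (length
  `tau`, default 4 bases) toward the uniform 0.25 — mirroring how
  real flank composition balances out with distance, and making
  recovery difficulty tunable.  `default_profiles()` generates
  families in which every pair of classes differs in at least one
  flank preference; a family whose classes differ only in the
  substituted base is a much harder target, since the distinction
  rests on a single matrix row.
* `generate_cohort()`: each SBS draws a hidden class from its
  patient's archetype mixture; sites are placed on non-overlapping
  genome windows and the flanks are overwritten in a scratch copy of
  the genome to follow the class profile, so `extract_flanks()` on
  the written FASTA/MAF reproduces the planted context exactly.
  Survival is exponential with per-archetype hazards under
  independent uniform censoring (a deliberately simple mechanism).
  Hidden truth goes to a separate file that the clustering path never
  reads.  Per-patient SBS counts are Poisson by default; the canned
  fixtures use fixed counts so their sizes are exact.

The canned fixtures (`write_fixtures()`) use flank length 10 and
planted profiles with `p_max = 0.9`, `tau = 6`: a two-class set (2000
SBSs), a ten-class set (1500 SBSs) and a survival cohort (200
patients, hazard ratio 3).  Under the true generative model the
Bayes-optimal classifier is essentially perfect on these sets, so
recovery failures indicate method limitations, not information-
theoretic impossibility.  These problem sizes keep a full test run in
the tens of minutes on one CPU; they are reduced-scale stand-ins, and
passing them shows the machinery works as specified — not that ten is
the right number of classes for real tumor cohorts, nor that real
signatures are as cleanly separated as the planted ones.  Real
mutation data add strand asymmetries, regional mutation-rate
variation, copy-number structure and shared context between nearby
substitutions, none of which the generator emulates.

## Numerical choices and degenerate inputs

* Winner ties break to the lowest unit index; the rank-based threshold
  counts the winner itself as rank 1 (a coincident layer gives S = 0).
* Chromosome-end flanks are padded with N, which has its own base
  code, so input length is always 2F + 1.
* A reference-allele mismatch against the genome is an error by
  default (drop and keep modes exist); silent correction is never
  performed.
* Degenerate splits (a candidate group under 2% of samples) score zero
  clarity, so the snapshot selection cannot prefer them.
* Inputs smaller than two batches shrink the batch with a warning;
  leaves too small to split are left intact with a warning.

## Known limitations

* The alternating dynamics resolves the dominant context contrast per
  round; distinctions carried by the mutation row alone (identical
  flanks, different base change) survive only when the anchored
  readout's input-space clusters capture them.
* The recursive schedule cannot merge: a sample separated from its
  class early can never rejoin it, which is why readout purity is
  guarded so carefully.
* The fixed 3+2 schedule presumes roughly balanced class sizes; very
  uneven planted mixtures can leave two true classes sharing a leaf
  while a pure class is split.
* Training cost is dominated by the LSTM passes; the pure-R
  implementation is adequate at fixture scale (seconds per round) but
  a corpus of millions of SBSs would need a compiled backend.
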