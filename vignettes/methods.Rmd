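---
title: "Methods: known-site tokens for PTM site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: known-site tokens for PTM site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the model, the conventions, and the design decisions
behind `modsite`, in the spirit of a methods section: what is computed, what
is assumed, and where the design was genuinely open.

## 1. Data representation

A prediction instance is a k-mer of odd length k centered on a candidate
target residue. The token alphabet is fixed: `-` (no amino acid, used to pad
windows that run past a terminus) has code 0; the 20 canonical amino acids
take codes 1–20 in alphabetical order (A→1, C→2, D→3, …, Y→20); `U`
(selenocysteine) takes 21; known-site tokens `@` and `&` take the next
codes. Non-standard residue letters (X, B, Z, J, O) are normalized to `-`
with a warning — public FASTA files contain them, and rejecting whole
proteins for one ambiguous residue is disproportionate. A strict mode
refuses them instead.

At most two mod tokens exist. A modification acting on two residue types
(phospho-S/T) uses one token per residue by default (`@` = modified S,
`&` = modified T), which keeps the mapping invertible; a single-token mode
collapses the channel onto `@` for users who prefer it. Requesting more than
two token classes is a configuration error: the symbol budget is part of the
scheme.

**Center masking.** The window's center is always emitted as the unlabeled
residue, even when the queried site appears in the known-site channel. The
center's own status is the prediction target; exposing it would leak the
label for every known-positive query. Neighboring known sites remain
visible — they are the input signal this package exists to exploit. Whether
training positives should instead carry their own token at the center is a
judgment call; we mask because it makes train-time and query-time inputs
identical by construction.

Positions are 1-based and inclusive everywhere (files, errors, APIs),
matching UniProt site-list conventions.

## 2. Classifier and training regimen

The network is: embedding (vocabulary × 21, learned from uniform ±0.05
initialization) → 2D convolution whose kernel spans the full embedding
width → ReLU → max pooling over the position axis → dense ReLU → dropout →
dense sigmoid. Training minimizes binary cross-entropy with Adam
(learning rate 0.001), batch size 100, at most 400 epochs, early stopping
with patience 15 on validation loss, and L2 weight 1e−6 applied to the
convolution kernel only. These values are the published regimen for this
model family and are all exposed in `model_config()`.

Sizes the regimen does not pin down are package conventions, chosen once:

* `conv_filters = 64`, `conv_kernel = c(7, 21)`: on a (k × 21) embedded
  plane, a full-width kernel is the only reading under which a "2D"
  convolution differs meaningfully from dense mixing of embedding
  dimensions; height 7 covers a typical linear-motif footprint.
* `pool_size = 4` (non-overlapping, remainder positions dropped — the usual
  framework default), `dense_units = c(128, 1)`.
* Dropout sits between the two dense layers (the literal reading of
  "two dense layers with a dropout in between"), not after the convolution.
* Early stopping restores the best-validation-loss epoch's weights, not the
  last epoch's: monitoring validation loss is only useful if the best
  checkpoint is kept.
* The embedding row of the padding token is trainable (not frozen at zero);
  a frozen variant changed nothing measurable on the synthetic tasks.

The network and its backpropagation are written in vectorized base R
(im2col matrix products); correctness is pinned by a finite-difference
gradient check in the test suite. This buys two things: no heavyweight
runtime dependency, and exact gradients with respect to the *embedded
input*, which integrated gradients needs.

## 3. Dataset construction

Candidates are enumerated over every occurrence of a target residue in the
supplied proteins. By default the candidate universe is the proteins that
appear in the positive site list — the "proteins that have the PTM"
negative convention — so negatives come from proteins known to be
substrates, not from arbitrary sequence space.

Negatives are subsampled uniformly to match the positive count (class
prevalence exactly 0.5); a `skip` flag preserves already-balanced datasets
such as sequon-restricted glycosylation sets. Splits are 80/10/10 at random
at the site level; a protein-level split is known to be less leak-prone but
site-level splitting is the convention this design follows, with the leak
controlled instead by identity filtering.

**Identity filtering.** After every split, any test window whose token
string exactly equals a train/validation window is removed — this guarantee
is always on. Below 1.0, identity between two windows is ungapped
position-wise identity (matching positions ÷ k), with mod tokens matching
only themselves. For fixed-length centered windows this Hamming-style
identity is the natural analogue of short-sequence clustering tools;
re-implementing a clustering heuristic's word filters would add complexity
without changing what is measured. Filtering removes test-side records
only; re-clustering the whole pool is a defensible alternative the package
does not take, because it changes the training distribution between
compared models. Removal at cutoff c is by construction a superset of
removal at any higher cutoff.

Monte Carlo cross-validation resplits *and* redraws the negative subsample
each fold from deterministic per-fold seeds; fold statistics are reported
as mean ± standard deviation. The paired labeled-versus-unlabeled
comparison uses identical fold seeds for both arms, so fold membership is
shared and a two-sided paired t-test on per-fold AUC is well-founded (a
Wilcoxon signed-rank option exists). The choice of t-test is ours; the
underlying significance convention (p < 0.05) does not name a test.

## 4. Evaluation

AUC is computed from average ranks, which is exactly the Mann–Whitney
concordance probability with ties credited ½, and equals the trapezoidal
area of the reported ROC points (tie groups collapse to single vertices, so
the diagonal segment through a tie block is the ½-credit). AUPRC uses
step-wise interpolation (precision at each threshold × recall increment);
linear interpolation in PR space is optimistic and is deliberately not
used. Headline metrics are threshold-free; the 0.5 threshold appears only
in the convenience `call` column of prediction CSVs.

## 5. Integrated gradients

For input embedding tensor `x` (k × n) and baseline `x'`:

ig[i,j] = (x[i,j] − x'[i,j]) · (1/m) · Σ_{s=1..m} ∂F/∂x[i,j] at
x' + (s/m)(x − x'),

a right-Riemann sum (s runs 1..m: includes the input endpoint, excludes the
baseline) matching the k/m scaling of the published formula. PSIG[i] is the
sum of row i over embedding dimensions. Conventions:

* **Baseline**: the embedded all-`-` sequence by default — the no-amino-acid
  token is the semantically neutral input, and it makes the attribution of
  terminal padding exactly zero. A zero-tensor baseline is available. The
  original formulation leaves the baseline unspecified; this is our
  declared default.
* **m = 64** by default; completeness error |Σ ig − (F(x) − F(x'))| decays
  as O(1/m) and is checked empirically at m ∈ {8, 32, 128, 512} in the
  tests. A heavily saturated model (trained to separate a noiseless task)
  has a larger completeness constant; the test fixtures therefore train on
  tasks with 15% label noise, which is also the more realistic regime —
  real PTM datasets are noisy.
* **Output scale**: attributions target the sigmoid probability by default;
  a logit mode exists, used by the closed-form oracle (a sigmoid-headed
  network can only be linear in the embedding on the logit scale).

Attribution tensors (before position summation) are clustered with K-means
(default 10 clusters, fixed seed, raw values; a standardization flag
exists). An inertia-versus-k elbow curve is always computed so the cluster
count is auditable. The 2-D visualization coordinates are the first two
principal components: no t-SNE implementation is available in this
dependency set, rendering is explicitly out of scope, and PCA has the
advantage of determinism. Per-cluster position×token frequency matrices are
truncated to ±10 residues around the center and include the mod-token rows,
so known-site enrichment shows up directly in a logo.

## 6. Proximity analysis

For each candidate, known sites at signed offsets −w..w (w = 26 by default,
the half-window of k = 53; offset 0 excluded — it is the candidate itself)
are counted, clipped at protein boundaries, and normalized by the number of
candidates so histograms are comparable across datasets. The histogram
shape is classified with declared thresholds: periodic if the detrended
autocorrelation of each histogram half peaks at the same lag with z > 3
against the non-multiple lags (a true comb lights up all multiples of its
period, so those cannot form the null); else decaying if Spearman ρ of
count versus |offset| < −0.5; else uniform if the coefficient of variation
< 0.15; else irregular. The labels follow the three empirical patterns seen
in real PTM data (evenly spread, repeat-driven, distance-decaying); the
"irregular" fallback exists because a declared-threshold classifier should
refuse to force a label. Diagnostics are always reported with the label.

## 7. Synthetic proteome generator

The generator states a world in which the central claim is testable without
downloads:

1. Sequences are i.i.d. from the background (uniform by default; a
   natural-abundance preset exists). Lengths are uniform on 200–400 for
   the default 300 proteins.
2. The number of positives is Binomial(n_targets, base_rate) with
   base_rate = 0.05 — a realistic prevalence for modified target residues
   among S/T.
3. A fraction `ptm_dependence` (default 0.7) of positives come in nearby
   pairs: an anchor placed uniformly plus a partner at a signed offset
   drawn with probability ∝ 1/|offset| from ±1..5 (producing the decaying
   proximity pattern). At full dependence the positive count is forced even
   and anchors whose partner cannot be placed are dropped, so "every
   positive has a nearby known site" holds exactly.
4. A consensus motif (offsets −3, −2, +1, +2 → R, R, P, L) is written
   around *anchors only*, each position independently with probability
   0.4. Partners carry no motif: they are modified because of crosstalk,
   not sequence, so their status is discoverable only through the label
   channel (or the anchor's context). This is the crux of the design — if
   partners also carried motifs, sequence alone would reveal nearly
   everything the labels encode and the labeling benefit would be
   structurally suppressed. The motif strength is chosen so that sequence
   alone supports good-but-imperfect prediction, leaving headroom for the
   labels, which mirrors the situation in real phosphoproteome data.
5. The known-site channel is the positive list with each site dropped
   independently with probability `label_noise` (default 0.2), emulating
   the incompleteness of PTM databases. A cross-type mode plants the
   partners as a second modification channel instead.

What a green test on this world establishes: the pipeline is correct, the
labeling mechanism captures planted crosstalk, and the labeled model beats
the unlabeled one when crosstalk exists (and not when it does not). What it
does not establish: performance on real proteomes, where motifs are softer,
composition is biased, homology structures the data, and label noise is
not independent. The generator makes no attempt to mimic any organism.

## 8. Known limitations

* Pure R training is adequate at desk scale (hundreds to thousands of
  records) but not for proteome-scale datasets with 10^5+ sites.
* Identity filtering is ungapped and window-local; genuinely homologous
  proteins with indels can evade it. A split manifest hook allows
  substituting an external clustering tool's verdicts.
* The 500-positive floor on the train-your-own-model workflow is a
  guideline, not a guarantee; it can be overridden, with a warning, for
  exploratory use.
* Model archives are RDS files: portable across platforms for this package
  version, but not a cross-language interchange format.
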