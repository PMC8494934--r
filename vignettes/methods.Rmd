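---
title: "Methods: temporally informed multi-omic network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporally informed multi-omic network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicGRN)
```

# Overview

`omicGRN` reconstructs signaling-to-transcription regulatory cascades from
matched time-course experiments quantifying three molecular layers —
transcripts (RNA-seq counts), proteins and phosphosites (isobaric-label,
e.g. TMT, reporter intensities) — under a two-condition (mock vs treated)
replicated design. The pipeline runs, in order:

1. **TMT normalization**: within-run sample-loading scaling, then
   between-run internal-reference scaling.
2. **Differential expression**: per-timepoint treated-vs-mock calls with
   layer-specific thresholds.
3. **Temporal clustering**: dynamic time warping (DTW) over combined
   regulator/target response profiles (independent component analysis for
   non-temporal designs).
4. **GRN inference**: cluster-restricted, timepoint-specific tree-ensemble
   importance of transcription-factor (TF) regulators for transcript
   targets, with separate regulator and target matrices; per-timepoint
   subnetworks are union-merged.
5. **Kinase-signaling network**: correlation-thresholded edges from
   activation-loop (p-loop) phosphosites of kinases to all differentially
   expressed phosphosites.
6. **Network Motif Score (NMS)**: per-gene participation counts in four
   directed motifs, max-normalized and summed, to rank candidate
   regulators.

A synthetic-data module generates a full multi-omic time course with a
planted kinase → TF-phosphosite → transcript cascade and scores how well
the inference recovers it.

# Normalization model

Isobaric-label intensities carry two nuisance factors: unequal material
per channel within a run, and run-to-run (batch) shifts. Sample-loading
normalization rescales every channel of a batch so its total intensity
equals the batch's mean column total; this assumes the bulk of the
signal is not differential, which holds when unchanged high-abundance
features dominate totals. Internal-reference scaling then uses the pooled
reference channels carried in every run (two per run in the supported
design; their per-feature arithmetic mean is the batch reference value).
For feature $i$ in batch $b$ with reference mean $r_{ib}$, the batch
factor is

$$ f_{ib} = \frac{\left(\prod_b r_{ib}\right)^{1/B}}{r_{ib}}, $$

i.e. the geometric mean across batches divided by the batch's own value.
The geometric mean is the natural center for multiplicative batch
effects; after scaling, every retained feature's reference means agree
across batches to numerical precision (this is asserted by the tests).
Features lacking a positive reference quantification in any batch cannot
be placed on the common scale and are dropped with a report. Missing
non-reference values stay missing — scaling never imputes.

# Differential expression

For every feature and timepoint, fold change is the ratio of treated to
mock replicate means; transcript counts are first scaled to
counts-per-million so library size cancels. Layer thresholds follow the
conventions of the platforms: transcripts are called at
Benjamini–Hochberg q < 0.05 with fold change beyond 1.25 (or its
reciprocal); proteins and phosphosites at raw p < 0.05 with fold change
beyond 1.1. Multiple-testing correction is within-timepoint, mirroring
per-timepoint contrasts.

The two-sample test is pluggable. The default is layer-dependent: the
exact Wilcoxon rank-sum test for the proteomic layers, and a Welch t-test
on log2(CPM + 0.5) for transcripts. The distinction matters at small
replicate numbers: with four replicates per condition the exact rank-sum
test cannot produce a two-sided p below 2/70 ≈ 0.029, so a BH q-cutoff of
0.05 essentially never fires unless most features are differential; the
t-test on the near-log-normal count scale is well calibrated and yields
continuous p-values, which the q-based transcript rule requires.

Features quantified in fewer than half of a condition's replicates at a
timepoint are skipped there and flagged; a zero mock mean yields an
infinite fold change that is excluded from calling with a warning.

# Temporal profiles and clustering

Each feature is summarized as a per-timepoint log2 treated/mock ratio,
z-scored across timepoints, so that response *shape* rather than
amplitude or layer drives clustering. Regulator profiles (TF protein or
phosphosite) and target profiles (transcripts) are row-bound into one
clustering matrix; a feature id present in both roles gets suffixed row
ids and is clustered independently in each role.

DTW with absolute-difference local cost and an unconstrained warping
window compares profiles; with six timepoints a warping-window constraint
would be moot. Profiles are agglomerated with average-linkage
hierarchical clustering on the DTW distance matrix and the tree is cut at
`k` clusters; when `k` is not given it maximizes the mean silhouette
width over k ∈ [2, min(15, n−1)]. Average linkage plus silhouette
selection was chosen because it is deterministic and directly testable;
`k` remains user-overridable. Clustering restricts the candidate
regulators of each target to same-cluster TFs, which both reduces the
edge search space and injects the temporal structure into the inference.

For non-temporal designs, `icaCluster()` decomposes the feature-by-sample
matrix with FastICA (symmetric scheme, logcosh contrast, seeded
deterministic initialization, implemented in the package) and assigns
each feature to the component with maximal absolute loading; component
signs are arbitrary, so assignment is sign-agnostic.

# Tree-ensemble inference

For each target, the regulator importances come from an Extra-Trees
regression ensemble (1000 trees, `mtry = ceiling(sqrt(p))` candidate
predictors per randomized split, impurity importance), normalized to sum
to one per target — higher weight, higher confidence in the edge.
Regression operates on log2(x+1) intensities, the scale on which
expression effects are approximately additive. Regulator rows are sorted
internally and a per-target seed is fixed, so results are reproducible
and independent of input row order.

Two design choices deserve emphasis:

* **Full-series regression, timepoint-restricted membership.** A
  timepoint's subnetwork restricts *which* regulators and targets
  participate (those differentially expressed there), but the regression
  always uses the full time-course sample set: eight samples per
  timepoint cannot support a tree ensemble, while the full series can.
* **Lag alignment.** In a transcriptional cascade the regulator's
  abundance at one timepoint acts on target transcription at a later
  one. `lagAlign()` therefore pairs each target sample with the
  regulator sample of the same condition and replicate one timepoint
  earlier (`lagSteps = 1` by default; `0` gives contemporaneous
  regression). On the synthetic cascade, which delays target responses
  by one step, contemporaneous regression loses most of the recoverable
  signal, while the lag-aligned regression recovers it.

Edges are retained per target when their weight exceeds
`mean + thresholdSD · sd` of that target's weights (default
`thresholdSD = 1`; a per-target adaptive cutoff keeps hub targets from
flooding the network). The rule is deliberately strict: when a target has
two comparable true regulators, the importance mass may split unevenly
and the weaker one can fall below one standard deviation above the mean;
`thresholdSD = 0` (above-average) or `topN` retention are available when
recall matters more than parsimony. A target with a single candidate
keeps it when its weight is positive. Subnetworks from the six timepoints
are merged as a union of edge records; an edge supported at several
timepoints keeps one record per timepoint, and conflicting duplicate
records keep the strongest weight so the union is order-invariant and
idempotent.

In phosphosite mode each differentially expressed phosphosite of a TF is
its own regulator row labeled `gene@site`, so different sites of one TF
can predict different targets; edges carry the predictive site label.
In abundance mode each TF contributes its protein profile when the
protein was quantified and its transcript profile otherwise.

# Kinase-signaling network

Phosphorylation of the kinase activation loop (p-loop) reflects kinase
activity, so DE phosphosites lying within their protein's p-loop interval
(1-based inclusive coordinates, consumed as an input table) qualify the
kinase as a potential signaling regulator. For every regulator site and
every DE phosphosite target, Pearson and Spearman correlations are
computed over paired non-missing samples across the whole series (both
conditions — pooling maximizes power, and the threshold rule is
correlation-based, not inferential); an edge is kept when Pearson ≥ 0.5
**or** Spearman ≥ 0.6, one-sided. The weight is the larger coefficient
and both are carried as columns. Self-pairs and pairs of sites on one
protein are excluded — a kinase "regulating" its own sites is not a
signaling prediction. An `absolute` flag thresholds |r| for exploratory
use. Pairs with fewer than three shared observations or a constant
profile are skipped and noted.

# Network Motif Score

Networks are collapsed to distinct gene-level directed pairs before
counting. Four motifs are counted per gene, in any role: feed-forward
loops (A→B, B→C, A→C), feedback loops (the 2-node mutual cycle; longer
cycles are not counted), diamonds (A→B, A→C, B→D, C→D with unordered
intermediates and A ≠ D) and bi-fans (A→C, A→D, B→C, B→D with unordered
source and target pairs, all four distinct). Matching is non-induced:
extra edges among the participants do not disqualify an instance —
the common convention of graphical motif matchers. Counts are computed
with adjacency-matrix algebra and validated against a brute-force
enumerator over node tuples. Each motif-type count is divided by its
maximum over genes (0 when the maximum is 0) and the four normalized
scores are summed, giving an NMS in [0, 4]; ranks are dense and
descending with ties shared. Enrichment of a user-supplied gene set among
network regulators uses the upper-tail hypergeometric test.

# Synthetic cascade generator

The generator emulates a 6-timepoint (15, 30, 60, 120, 240, 480 min) ×
2-treatment × 4-replicate design. Its defaults are the package's study
conditions:

* **Activation curves.** Each kinase's activation-loop site follows a
  log-time Gaussian pulse under treatment (peak times 12–120 min, widths
  0.3–0.6 log-units); mock profiles stay flat. Each TF inherits a pulse
  peaking later than its planted kinase, with onset times spread across
  the whole time course — the waves of early and late regulators typical
  of hormone responses — and widths 0.25–0.55 spanning transient to
  sustained. This shape diversity is what makes regulators statistically
  separable with only six timepoints.
* **Responses.** TF phosphosites respond to their kinase with signed
  amplitudes of 1–2 log2 units (2–4-fold); TF protein tracks the same
  activity (transcript at 0.7×); target transcripts are signed linear
  responses to their 1–3 planted TF regulators delayed by one timepoint
  (`lag_steps = 1`). A linear-with-lag response, rather than ODE
  dynamics, is sufficient to encode the cascade's temporal structure and
  cheap to verify.
* **Noise and batches.** Replicate noise is multiplicative log-normal
  with log2-scale sd 0.2 (~15% CV). Proteomic samples are assigned to
  replicate-wise isobaric batches, each with two pooled reference
  channels (per-feature geometric mean of all true sample values) and a
  multiplicative batch offset (log-sd 0.3), so both normalization steps
  are genuinely exercised.
* **Nulls.** Kinase protein abundance, one non-p-loop site per kinase
  and 30 high-abundance flat "bystander" features per layer are true
  nulls. The bystanders deliberately dominate library/loading totals, as
  unchanged bulk signal does in real data; without them the small
  simulated matrices would violate the compositional assumption behind
  sample-loading and CPM normalization.

What the generator does *not* emulate: missing-at-random quantification
dropout patterns of real TMT searches, count overdispersion of RNA-seq,
feedback from targets onto regulators, and shared-kinase correlation
structure beyond what the planted wiring implies. Passing tests therefore
demonstrate the computational correctness and the statistical behavior of
the pipeline under its own model, not performance on any real data set.

Recovery is scored by `evaluateRecovery()`: the ranked regulator–target
list is compared with the planted edges over the full candidate universe;
area under the precision–recall curve (tie-aware, trapezoidal over tie
groups) is reported alongside planted-edge prevalence, AUROC (midrank U
statistic) and the median planted-edge rank. Note that with six
timepoints the profiles span a low-dimensional space, so 1–3-regulator
mixtures are only partially identifiable no matter the method; the
benchmark's AUPR should be read relative to prevalence, and the package's
tree-ensemble ranking compares favorably with sparse-regression
alternatives under the same conditions.

# Numerical and degenerate-input policy

* Coordinates (phosphosite positions, p-loop intervals) are 1-based
  inclusive, matching amino-acid numbering.
* Missing values are first-class: parsers keep empty cells as `NA`,
  normalization never imputes, correlations use pairwise-complete
  observations with a minimum pair count, and the DE module states its
  skip rule.
* Constant profiles: z-scoring maps them to zero rows; importance scoring
  returns flagged all-zero weights for a constant target and zero weight
  for a constant regulator; correlation pairs with a constant member are
  skipped with a note; the QC projection of a constant matrix is all
  zeros rather than an error.
* Determinism: every stochastic step (tree ensembles, ICA initialization,
  the generator) takes a seed; the pipeline fans one top-level seed out
  to its stages and records it in the manifest, and repeated runs are
  byte-identical.
* Problem sizes in the shipped tests are chosen to keep the whole suite
  in the minutes range on one CPU: oracle comparisons use ≤12-point
  series and ≤8-node graphs, the recovery benchmark uses the default
  10-TF × 100-target configuration over 10 seeds, and pipeline smoke
  tests use a reduced 6-TF × 25-target configuration.

# Known limitations

* The per-target retention threshold interacts with the number of true
  regulators; the default favors precision (see above).
* Feedback loops are counted only as 2-node mutual cycles.
* The DE module tests each feature independently; no spline or
  time-course joint model is fitted, and no imputation is attempted.
* Phosphosites mapping to multiple protein groups must be collapsed to a
  single gene id upstream; the annotation model requires one gene per
  feature.
* P-loop coordinates are consumed as an input table; discovering them
  from sequence is out of scope.
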