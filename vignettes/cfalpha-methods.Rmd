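---
title: "Read-level cfDNA methylation analysis: models, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-level cfDNA methylation analysis: models, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfalpha)
```

This vignette documents the scientific model behind `cfalpha`, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the decisions taken where the design was genuinely open. It
states no empirical result that the package's tests and acceptance script
do not themselves compute.

## 1. Marker unit regions

An RRBS-style assay enriches CpG-rich DNA by digesting with MspI, which
cuts `C|CGG`. The unit of all downstream analysis is the interval between
two adjacent cut coordinates that is shorter than 350 bp (strictly; the
bound excludes fragments too long to be captured efficiently). Coordinates
are 0-based half-open throughout and in BED output. The cut coordinate is
`motif start + 1`, so each region begins `CGG…` and ends `…C`; because
`CCGG` is its own reverse complement, a plus-strand scan finds every site.
Two conventions the assay leaves open:

* **N handling.** Regions overlapping a run of ≥ 10 `N` bases are dropped
  (configurable); ambiguity codes never match the motif.
* **Fragment assignment.** A fragment belongs to the region containing its
  midpoint. Digested fragments normally coincide with regions, making the
  rule exact for them, and it degrades gracefully for WGBS-like reads that
  straddle a boundary.

## 2. The α-value and read-level discovery

The α-value of a read is the fraction of methylated CpGs among the CpG
sites it covers. Reads covering fewer than `min_cpg = 3` CpGs are excluded
from α analyses: with 1–2 CpGs, α is a quasi-binary coin flip that carries
almost no information about the molecule's methylation state, and a read
with zero covered CpGs has no α at all. The floor is configurable; 3 is a
compromise between noise suppression and read retention in CpG-sparse
regions.

Discovery asks, per region and direction, whether case samples contain a
well-separated population of directional reads — hypermethylated
(α ≥ α_hyper) or hypomethylated (α ≤ α_hypo) — that control samples lack.
The package operationalises this as:

1. For every threshold on the grid {0, 0.05, …, 1} and every case/control
   pair, test whether the case's directional read count is enriched by the
   one-sided Fisher exact test on the 2×2 table
   (directional vs non-directional) × (case vs control).
2. Learn the threshold maximising the number of pairs with p < 0.05;
   ties break toward the more extreme threshold (largest for hyper,
   smallest for hypo), preferring the cleaner separation.
3. Keep the region if at least `support_frac = 2/3` of pairs support it —
   the count of supporting pairs is the marker's stability — and rank by
   (support, mean directional-fraction difference).

The exact separation statistic used by the original read-level method is
not fully specified at this level of detail anywhere we could build from,
so the Fisher-count objective is this package's defining operational
decision; every knob (grid, `p_cut`, `support_frac`, `top_m`) is exposed in
`discovery_params()`. No FDR correction is applied across regions by
default — selection is rank-based, mirroring top-M marker analyses — but a
Benjamini–Hochberg mode (`fdr = TRUE`) is available.

**Pairing.** Tumor/adjacent-normal contrasts are natively paired. Unpaired
contrasts (tumor type vs tumor type, tissue vs tissue) reuse the paired
machinery through seeded random pseudo-pairing repeated 5 times with the
support surface averaged; this is an interpretation, chosen so one
statistic serves all contrasts. Both ordered directions of each contrast
are emitted (an A-enriched and a B-enriched marker are distinct), and
duplicated regions across merged contrasts keep their best-ranked instance,
including its learned threshold.

**Reference filtration.** Cancer markers must be quiet in plasma of
noncancer individuals: a candidate passes if, in ≥ 90% of the reserved
reference plasma samples, the directional read fraction at the candidate's
own threshold is ≤ 5%. Reference samples with no reads in the region pass
by construction (their directional fraction is 0). Because the reference
set is re-drawn per validation run, panels legitimately differ slightly
across runs, and the pipeline re-derives them each run.

## 3. Feature profiles

For each marker family the sample's profile vector holds, per marker, the
count of directional reads at that marker's own learned threshold (each
marker keeps the threshold it was discovered with), normalised by
sequencing depth and log-transformed:

`value = ln(1e9 · count / raw_read_count + 1)`.

`raw_read_count` is the sample's total mapped deduplicated fragment count,
taken from the metadata rather than recomputed, since upstream filtering is
outside the package. The transform is zero exactly for zero counts,
strictly increasing, and invariant under joint rescaling of count and
depth. Every profile matrix carries a fingerprint of the panel it was
built against, and models refuse profiles built against a different panel.

## 4. The stacked ensemble

The four profile types live on different scales (hypermethylated cfDNA is
better nucleosome-protected and more abundant; tissue signal has a baseline
in blood that cancer signal lacks), so they are combined by stacking
rather than concatenation:

* **Level 1** — per family, a linear SVM with L2 penalty and C = 1 on
  per-feature standardised profiles (centring/scaling fitted on training
  data; scales differ across markers and the solver is not
  scale-invariant). Detection uses a binary machine per view;
  tissue-of-origin uses one-vs-rest machines.
* **Level 2** — a random forest with 2000 trees; other forest
  hyperparameters stay at the `randomForest` defaults and are recorded in
  the model object. Its inputs are the stacked level-1 outputs: the signed
  decision score of each view for detection (4 features), each view's
  per-class one-vs-rest scores for TOO (4 × n classes features). What
  exactly "the predictions" of level 1 should be is an open design point;
  decision scores retain margin information that hard labels discard.
* **Cross-fitting** — level 2 is trained on out-of-fold level-1 outputs
  from a stratified k = 5 split (k configurable, leave-one-out when
  k ≥ n), so the forest never sees level-1 training-set optimism. The
  level-1 models used at prediction time are refit on all training data.
* **TOO confidence** — one-vs-rest forest probabilities are normalised to
  sum to 1; the top type is called only if p(1st)/p(2nd) ≥ 2.5. A top-2
  tie gives confidence 1, hence no call; a runner-up probability of zero
  gives confidence ∞, hence a call. An empty marker panel (possible when
  reference filtration removes every candidate at desk scale) contributes
  a constant zero score rather than failing, keeping the four-view
  architecture intact.

Determinism: identical seeds and inputs give identical folds, forests and
predictions; the SVM solver is deterministic.

## 5. Evaluation protocol

Per run, 25% of cancer and 25% of noncancer plasma form the test set
(counts rounded half-up: a 217/191 cohort gives 54 + 48 test samples); 30
noncancer samples are then reserved from the remaining 75% for marker
filtration only, and the rest train the models. Ten runs are summarised by
the mean and the empirical 2.5/97.5 percentile interval (a normal-theory
`mean ± 1.96 sd` option exists; percentiles were preferred as the 10-run
distribution is small and possibly skewed).

"Sensitivity at one false positive" is the ROC operating point that
concedes exactly one test negative: samples scoring strictly above the
second-highest negative score are called positive. With tie-free negative
scores the specificity is exactly `1 − 1/#negatives` (47/48 = 97.9% at 48
test negatives); ties straddling the cut are resolved conservatively and
the achieved false-positive count is reported. Defining the operating
point by the midpoint between the top two negatives instead would
understate sensitivity whenever positives score between them, so the
ROC-step convention is used. Per-stage/per-type sensitivity is suppressed
for groups averaging fewer than 4 test patients per run. TOO accuracy is
computed over called samples only, with per-type precision
(#correct calls of the type / #calls of the type) and confusion matrices
accumulated across runs. The round-half-up rule and the 48-negative
consequence are asserted in the test suite.

## 6. The synthetic-methylome generator

The generator exists so discovery, profiling and classification are
testable against known truth. Its model:

* **Reference** — one synthetic chromosome whose `CCGG` motifs are placed
  so digestion yields exactly the requested regions (lengths uniform on
  60–300 bp, 3–8 CpGs each); planted `CG` dinucleotides are A/T-flanked so
  no spurious cut site can arise, and the digest round-trips exactly.
* **Methylomes** — a bimodal baseline (mixture of Beta(1.5, 8) and
  Beta(8, 1.5)) shared across sources; planted DMRs shift one source by Δ.
  Hypermethylation targets sit on unmethylated CpG-island-like baselines
  (U(0.02, 0.08)) and hypomethylation targets on methylated repeat-like
  baselines (U(0.92, 0.98)) — the genomic contexts such markers occupy in
  real methylomes, and the only baselines at which a 5% background
  directional fraction is attainable at desk-scale depth.
* **Reads** — per region and sample, `depth` reads; each read draws a
  source from its sample's mixture, a molecule level
  m\* ~ Beta(mκ, (1 − m)κ) around the source level m, and a
  methylated-CpG count ~ Binomial(n_cpg, m\*). The concentration κ = 5
  creates the heterogeneous, bimodal α distributions the read-level method
  exploits; κ → ∞ recovers a pure binomial. All three draws are
  quantile-coupled (each read consumes exactly three uniforms), so cohorts
  differing only in one mixture weight share all remaining randomness — a
  common-random-numbers design that makes the tumor-fraction dose-response
  comparison low-variance.
* **Samples** — per type: paired tumor tissue (a purity-0.6 mixture of
  tumor and matched normal methylome, reflecting tumor impurity) and
  adjacent normal, plus pure normal tissues; plasma is a read mixture of a
  tumor methylome at fraction f over a background blend of the normal
  tissues (liver-dominant weights 0.55/0.15/0.15/0.15, emulating the
  hepatic/hematopoietic dominance of cfDNA). Noncancer plasma is pure
  background.

**Default study conditions** (chosen once): 4 types (colon, liver, lung,
stomach), 200 regions, 20 tissue pairs and 10 normal tissues per type, 15
cancer plasma per type and 80 noncancer plasma, depth 30 reads/region,
κ = 5, Δ = 0.5, tumor fraction 0.1 — a mid-range value standing in for the
mix of early and late stages in a realistic cohort, scaled to desk-depth
detectability. The 40 planted DMRs are split evenly across the three
marker families: 4 + 4 pan-cancer, (2 + 2) × 4 type-specific cancer,
(2 + 2) × 4 tissue-specific.

**What the generator does not emulate:** sequencing errors, incomplete
bisulfite conversion, UMI collisions, fragment-length variation (fragments
span their whole region), copy-number effects, batch effects, and
inter-individual baseline variation beyond the molecule-level κ. Passing
tests therefore demonstrate correctness and sensitivity of the machinery
under the stated generative model, not clinical performance on real
cohorts — the headline numbers real studies report depend on restricted
patient data and sequencing depths orders of magnitude beyond desk scale.

## 7. Numerical choices and degenerate inputs

* One-sided Fisher tests are computed as vectorised hypergeometric tails,
  exact and fast across the region × threshold × pair lattice; the test
  suite proves equality with brute-force enumeration over all tables with
  total ≤ 40.
* AUROC uses the midrank (Mann–Whitney) formula, ties counting one half;
  proven equal to brute-force pair counting.
* A pair with zero reads on either side yields p = 1 (uninformative,
  flagged); a region with no significant threshold is dropped
  (support 0); empty inputs give empty outputs, not errors, except where
  a contract is violated (fewer than 2 samples per group, no reference
  samples for filtration, one-class training labels).
* Grid thresholds are closed boundaries: α ≥ thr for hyper includes reads
  exactly at the threshold, α = 1 reads are counted at thr = 1.
* Scalers guard zero-variance features (scale 1), and the SVM decision
  score is empirically oriented so that higher always means the positive
  class, independent of libsvm's internal label order.

## 8. Problem sizes in the test suite

The suite checks the planted-recovery guarantee at Δ = 0.5 with 10 pairs
and depth 30 over 20 generator seeds; the null false-marker rate over 200
no-signal replicates (20 regions each); the tumor-fraction dose-response
at {0.001, 0.01, 0.05, 0.2} with 10 replicate cohorts of 80 regions; and
the stacking guarantee on 10 replicates of four-view Gaussian data. These
sizes were chosen as the smallest at which the corresponding sampling
noise is well below the assertion tolerances, and they are the package's
own statement of the desk-scale study conditions.

## 9. Known limitations

* The Fisher-count objective is a stated stand-in for the original
  non-parametric separation statistic; rankings may differ near the
  decision boundary.
* Pseudo-pairing for unpaired contrasts averages over 5 random matchings;
  support values are then fractional and slightly seed-dependent.
* At desk-scale depth, reference filtration is severe: hyper markers
  whose background baseline exceeds ~10% methylation rarely pass, so
  cancer panels are much smaller than genome-scale studies report —
  expected behaviour of the filter, not a defect.
* The level-2 forest sees only 4 (or 4 × classes) features; with very few
  training samples its probabilities are coarse and the 2.5-fold TOO
  confidence gate abstains often. Accuracy over called samples remains
  the honest headline metric, reported alongside the no-call rate.
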