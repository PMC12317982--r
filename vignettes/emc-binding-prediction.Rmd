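---
title: "Predicting EMC chaperone engagement of transmembrane domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting EMC chaperone engagement of transmembrane domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emcbind)
```

## The problem

The ER membrane protein complex (EMC) is not only an insertase: its
lipid-exposed intramembrane cavity acts as a holdase-type chaperone that
binds transmembrane domains (TMDs) carrying suboptimal features — polar or
charged residues, helix breakers — until the client assembles or folds.
Which TMDs engage this site can be measured with a substitution scan on a
minimal consensus membrane protein (ConMem): single residues of an inert
~26-residue TMD (Pro/Lys flanked) are exchanged, and relative binding to
the endogenous EMC is quantified against the unmodified reference
(valine at the central position 13, affinity defined as 1).

`emcbind` turns such a scan into a sequence-based affinity predictor and
applies it proteome-wide, and also provides the two trajectory-analysis
statistics used to characterize bound TMDs structurally: residue–residue
contact numbers and helix tilt angles.

## The model

**Featurization.** Each amino acid is described by published property
scales (hydropathy, polarity, volume, charge, secondary-structure
propensity, ...), parsed from the AAindex1 flat format and min–max scaled
per index so all 20 residue values lie in [0, 1]. Two schemes map a TMD to
a feature vector:

* *v1 (position features)*: the scaled value of the residue at each
  scanned position (6, 9, 13, 17, 21).
* *v2 (subsequence features)*: the TMD is cut into 9 contiguous chunks
  whose lengths differ by at most one, longer chunks first
  (remainder-first). The feature is the mean scaled value over a chunk.
  Only chunks 2, 3, 5, 6 and 7 are used: for TMD lengths 25–26 these are
  exactly the chunks containing the scanned positions, and the scheme
  extends to TMDs of any length ≥ 9, which is what makes proteome-wide
  scoring possible.

The remainder-first convention matters: with remainder-last chunking the
position-to-chunk correspondence breaks for these lengths. It is asserted
by tests.

**Feature selection.** For every candidate (slot, index) pair the scaled
feature values are correlated with measured affinities over the variants
substituted within that slot, plus the reference variant. A pair is kept
iff |r| > 0.7 **and** the two-sided t-distribution P-value
(t = r √((n−2)/(1−r²)), n−2 df) is < 0.01; both inequalities strict.
Correlating a slot's feature across *all* variants instead would pool
unrelated positional effects into the vertical scatter and provably
dilutes every correlation below threshold, so the per-slot subset is the
only workable reading. By default selection sees the training split only,
keeping the held-out evaluation leakage-free; `select_on = "all"` is
available for comparison with pipelines that select before splitting.

**Regressor.** A single-hidden-layer neural network: 100 ReLU units, Adam
with initial step 0.001, L2 penalty 1e-4 on the weights, at most 1000
iterations, Glorot-uniform initialization from a recorded seed. Training
is full batch (the training sets, 44–57 variants, are smaller than any
customary minibatch). Feature vectors are already in [0, 1]; no further
standardization is applied, and affinities are fitted on the linear
reference-normalized scale (`transform = "log2"` is available but not the
default — measured binding ratios are reported linearly).

**Early stopping is off by default.** A loss-plateau rule
(improvement < tol for 10 consecutive iterations) is implemented and
available via `mlp_control(tol = ...)`, but with `tol = 0` the optimizer
runs its full budget. The reason is numerical: at these sample sizes
full-batch Adam traverses the large initial offset between the network's
near-zero output and the affinity mean with substantial momentum, and the
loss briefly *rises* for more than ten iterations while the overshoot
decays. A plateau rule fires inside that transient, freezing the model at
roughly the intercept fit. Running the fixed 1000-iteration budget is
deterministic, cheap (seconds), and converges reliably.

## The synthetic scan generator

`simulate_conmem()` emulates the structure of the measured dataset so the
whole pipeline is testable without the original measurements:

* a consensus-like backbone `r conmem_backbone()` (Leu/Ile/Val/Phe-rich
  24-residue core, Pro/Lys flanks, Val at 13);
* all 19 exchanges at position 13 plus the panel G, S, Y, P, E, D, K, R at
  positions 6, 9, 17 and 21; additional variants are drawn from the unused
  (position, residue) combinations;
* shapes matching the two training iterations: 59 variants split 44/15
  (v1) and 77 split 57/20 (v2), assigned uniformly at random from the
  dataset seed;
* a planted ground truth, linear in scaled properties: affinity
  = 1 + 2.2·Δpolarity (Grantham) + 0.5·Δhydrophilicity (Hopp–Woods),
  summed over the scanned positions, relative to the backbone residue.
  Two correlated components mirror the empirical situation in which many
  mutually correlated polarity-type indices track binding, and the weights
  size the strongest binders at roughly four times the reference — the
  dynamic range the measured scan shows. Affinities are truncated at 0;
  the reference variant carries no noise (it is the normalizer and is
  exactly 1 by construction);
* Gaussian noise on substituted variants, defaulting to 10% of the planted
  signal range.

What passing tests on these data do **not** show: real binding is not
exactly linear in any property set, positions interact, and measurement
error is not homoscedastic Gaussian. The generator validates the
machinery (selection calibration, recovery of a recoverable signal,
pipeline determinism), not the biological accuracy of any particular
trained model.

## Proteome scoring conventions

TMD records are oriented so the first residue sits on the exo (lumenal/
extracellular) side, mirroring the N-exo topology of the binding assay;
endo-start sequences are reversed, and UniProt-style location labels map
to sides via a fixed list (cytoplasm-type labels are endo; extracellular,
lumenal and organellar lumen-equivalents such as the mitochondrial matrix
are exo; unknown labels default to endo with a warning). Raw predictions
over the whole scored set are min–max normalized to 0–100 (a single-score
set maps to 0 by convention), and a protein's score is the maximum over
its TMDs. Because min–max is monotone, max-then-normalize equals
normalize-then-max; this and the order-statistics consequence — expected
protein score grows with TMD count under i.i.d. TMD scores — are asserted
by simulation in the tests. Normalization is computed globally over
whatever set is scored; restricting the input restricts the reference
frame, which is the documented behaviour.

## Trajectory statistics

The contact number between residues i and j is the time average over
frames of Σₖ Σₗ 1/(1 + e^{5(d_kl − 4)}), with d_kl the distance in Å
between heavy atoms k ∈ i and l ∈ j; the logistic midpoint 4 Å (0.4 nm)
scores 0.5, contacts below it approach 1, larger distances approach 0.
Minimum-image distances are used only when an orthorhombic box is
supplied. The helix tilt is the angle between the membrane normal and the
principal axis (largest-eigenvalue eigenvector of the coordinate
covariance about the centroid) of the helical region's heavy atoms,
folded to [0°, 90°] so axis sign is irrelevant. The stiff-helix assumption
is honored — no bending correction; if the top two eigenvalues nearly
coincide the axis is ill-defined and a warning is raised. Note that a
finite helix's principal axis deviates from its geometric axis by a
fraction of a degree (the incomplete final turn), which sets the ~1°
resolution quoted in the tests.

## Numerical choices and edge cases

* Constant property indices (max = min) and indices with missing residues
  are rejected before scaling; non-canonical residues (X, B, Z, U) in a
  query impute mid-scale (0.5) with a warning.
* Selection thresholds are strict inequalities; ties in feature order are
  broken by (slot, accession) so specs are reproducible.
* Model JSON files serialize weights as 17-significant-digit strings, so
  reloaded models reproduce predictions bit-exactly.
* Duplicate sequences with conflicting affinities, ragged lengths and
  negative affinities are load-time errors; an all-excluded proteome scan
  is an error rather than an empty result.
* All randomness (dataset generation, splits, weight initialization,
  simulation) flows from explicit integer seeds that are recorded in the
  objects and model files.

## Problem sizes used in the test suite

The shipped tests and the acceptance script use the assay-shaped dataset
sizes (59 and 77 variants), 20-seed medians for the recovery studies,
1000-permutation nulls for selection calibration, 1000 synthetic proteins
for the scoring invariants, and 10-frame toy trajectories for the
geometry oracles. These sizes were chosen so the full suite runs in about
two minutes while keeping Monte-Carlo error well below the asserted
margins.

## A complete example

```{r example}
ds <- simulate_conmem(seed = 7)
fit <- emc_fit(ds, seed = 7)
summary(fit)
evaluate(fit)

recs <- data.frame(
  protein_id = c("P1", "P1", "P2"),
  sequence = c(conmem_backbone(),
               gsub("V", "R", conmem_backbone()),
               gsub("LL", "QS", conmem_backbone())),
  start_side = c("exo", "endo", "exo"))
scored <- score_proteome(fit, recs)
scored$protein
```

## Known limitations

The predictor interpolates within the property space spanned by its
training scan; residues or positions never scanned are extrapolation. The
bundled index table holds 20 scales, not the full AAindex database, so a
selection run against it explores a smaller candidate pool than a full
installation would. Proteome-level summary statistics depend on the input
TMD inventory and on the trained model, so absolute 0–100 scores are only
comparable within one scored set. The geometry module analyzes
coordinates it is given; it does not validate force fields, sampling, or
the choice of the helical-region selection.
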