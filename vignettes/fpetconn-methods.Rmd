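---
title: "Methods: multimodal metabolic connectomics on synthetic cohorts"
author: "fpetconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal metabolic connectomics on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, parameters, numerical choices and known
limitations of `fpetconn`. It states no empirical result that the test suite
and `scripts/acceptance.R` do not themselves compute.

## The analysis model

Three connectivity constructions are computed for a cohort of patients (PD)
and healthy controls (HC):

* **sPET (static) covariance** — each subject's retained, intensity-normalized
  dynamic PET frames are summed into one static uptake image; regional
  uptake is correlated *across the subjects of a group* (Pearson), with
  per-edge p from the correlation t test on n − 2 degrees of freedom. This
  is the classical group-level "metabolic covariance" and has no
  subject-level analogue.
* **fPET connectivity** — each subject's regional uptake *time series*
  (last 30 of 90 one-minute frames, normalized) are correlated pairwise
  over frames; per-subject matrices are Fisher-transformed
  (z = atanh r, r clipped to ±(1 − 10⁻⁷)), averaged edge-wise over the
  group, and each edge is tested with a two-sided one-sample t of the
  subjects' z values against zero.
* **fMRI connectivity** — identical machinery over 490 BOLD time points.

Signed adjacency matrices keep edges with p < α (default 0.05; raw p — no
edge-level multiplicity correction, matching the construction the adjacency
emulates; multiplicity is handled downstream at the unit-degree tests).
Multimodal connectomes intersect two adjacencies edge-wise, requiring sign
agreement; the Sörensen–Dice coefficient DC = 2|M1 ∩ M2|/(|M1| + |M2|) is
computed on strict-upper-triangle edge sets, by default restricted to
positive edges (`reference = "positive"`; `"all"` is available for
whole-brain comparisons). The degenerate 0/0 case (both edge sets empty) is
defined as DC = 0 and flagged. Nodal degree is the number of retained edges
per region; unit-level group comparisons (patients vs controls, per
functional unit, over member regions) use a Shapiro-Wilk-gated two-sample
test with Bonferroni-Holm correction across the units of one connectome.
Subject-level motor degree — the count of significant edges per region
within the identified motor network at the subject level — is correlated
with severity by Spearman's rho (exact permutation p for n ≤ 9 without
ties, t approximation otherwise).

Two points where the construction is deliberately explicit:

* "Standardised" connectivity strength means Fisher z of r (the scale the
  matrices are reported on), not z-scoring across edges.
* The static image sums the *retained* frame window (61–90), not all 90
  frames, so the static and dynamic PET constructions see identical data;
  the window is configurable (`keep_last`).

## Group spatial ICA

Intrinsic networks are identified by spatial ICA of the temporally
concatenated group data: per-subject temporal means are removed (standard
for temporal-concatenation group ICA, otherwise between-subject baseline
offsets masquerade as components), a single-stage PCA reduces to
`n_components` = 10 dimensions with whitening, and symmetric
(parallel-update) FastICA with the logcosh contrast rotates to maximally
non-Gaussian spatial maps. Maps are z-scored over in-mask voxels; sign is
fixed by nonnegative spatial skewness. Components are thresholded one-sided
at z = 1.5 (z = 1 for the sensorimotor component, which tends to engage
cortical clusters more weakly) and parcellated against the atlas: regions
with at least `min_fraction` = 0.1 of their voxels inside the mask form the
network region set.

Numerical choices, and two departures from an earlier internal design that
implementation proved wrong:

* **Symmetric rather than deflation FastICA.** On mixtures of ten
  one-sided, disjoint-support spatial sources — exactly the geometry of
  intrinsic network maps — deflation-mode logcosh converges to poor optima
  (best spatial correlations 0.4–0.75 against truth in our fixtures, and
  the same behaviour reproduces in an independent implementation), while
  symmetric updates recover the sources essentially exactly. The package
  therefore uses symmetric updates with up to 5 seeded restarts
  (`max_iter` = 500, tolerance 10⁻⁷ on the rotation), and raises an error
  on non-convergence rather than returning a doubtful decomposition.
* **Detrended, not ratio-normalized, ICA input.** Constant-infusion PET
  carries a monotone uptake ramp that must be removed before decomposition.
  Dividing each frame by its global mean removes the ramp but injects a
  global regressor − b·δ(t) whose time course is the weighted sum of all
  network fluctuations. At a realistic whole-brain scale any single
  network's share of that sum is small; on a 30-region toy brain the motor
  network is ~20% of the global mean, the induced regressor correlates
  ~0.5 with the motor factor, and the independence assumption of ICA fails
  for precisely the component of interest (ablation shows the motor map is
  split or absorbed under every contrast function once the division is
  applied, and recovered cleanly without it). The decomposition therefore
  consumes per-voxel linearly detrended retained frames; the
  ROI-extraction/connectivity pathway keeps global-mean normalization,
  where Pearson correlation's per-series location/scale invariance makes
  the residual global coupling a realistic, mild global-signal effect
  rather than a model violation.

The sensorimotor component is selected as the component with the highest
mean z over the cortical-motor template regions; component correspondence
across groups or modalities is available via exact optimal assignment on
absolute spatial correlations (`match_components`, bitmask dynamic
programming, exact for the ≤ 18-component decompositions used here).

## The synthetic cohort generator

The generator defines the study conditions: 12 patients and 13 controls; a
3D toy atlas of 30 contiguous parcels (12 × 12 × 8 grid, ≥ 8 voxels per
parcel) assigned to seven functional units with cortical_motor = 6 regions;
90 one-minute PET frames; 490 BOLD frames.

**Latent structure.** Planted edges are unions of cliques ("communities"),
one latent factor per community. A member region i of community c with
weight w has fluctuation

x_i(t) = √w · G_c(t) + √(1 − w) · u_i(t),

with G_c and u_i unit-variance white (PET) or AR(1) (BOLD) processes, so
the model correlation of every planted edge is exactly w and non-planted
pairs are uncorrelated — the loading → correlation mapping is closed-form,
which is what makes the downstream Pearson estimators testable against
known targets. Regions in no community carry no fluctuation.

**Communities.** Each group has `n_networks` = 10 communities, matching the
decomposition dimension of the analyses: one community per functional unit,
with the largest non-motor communities split in half until ten exist. The
patient motor community spans all six cortical-motor regions; the control
motor community only the first three — the planted group contrast
(15 vs 3 motor-motor edges). An earlier design with one community per unit
plus per-edge factors left the 10-component space with room for per-region
contrast directions, which any ICA contrast function prefers to the broad
motor map (sparser is more non-Gaussian); matching the number of planted
networks to the decomposition dimension is the generative statement that a
10-component analysis presumes about its data.

**PET signal.** Voxel v of region i at frame t:
y_v(t) = b_i(t + a·x_i(t)·[t > 60]) + ε, with per-region baseline slopes
b_i ~ U(0.9, 1.1) (monotone accumulation under constant infusion),
fluctuation amplitude a = 2 confined to the final 30 frames (early frames
carry low signal — the frame-retention rule is what exposes the
fluctuations), and i.i.d. voxel noise σ = 0.5. **BOLD signal**: flat
baseline 100·b_i plus amplitude-3 AR(1) fluctuations (φ = 0.4) over all
490 frames; AR filtering leaves cross-correlations at w. **Static
covariance**: subject-level baselines b_i(s) = b0_i(1 + 0.05·z_i(s)) with
z_i(s) drawn from the same community model across subjects at
w = 0.75, planting across-subject covariance for the sPET construction.

**Disease coupling.** Each patient's motor community weight is
edge_strength × coupling, coupling ~ U(0.3, 1); severity =
10 + 35·coupling + N(0, 4) — an affine-monotone map plus noise, calibrated
so the recovered Spearman rho between severity and subject-level motor
degree at n = 12 is of the moderate magnitude the analysis is designed to
detect (the acceptance run prints the realized value; across fixture seeds
it varies roughly between 0.4 and 0.9). Edge strength defaults to 0.55 —
no effect sizes in correlation units are available to copy, so the value
is set to make planted edges clearly super-threshold at 30 frames
(critical r ≈ 0.36 at p < 0.05) for well-coupled patients while leaving a
detection gradient across the coupling range.

**Reproducibility.** One global seed expands into per-subject substreams by
a documented counter scheme (stream 2k for subject k's PET, 2k + 1 for its
BOLD, folded modulo 2³¹ − 2), so any subject regenerates individually and
the whole cohort is bit-identical under a fixed (config, seed).
`volumes = FALSE` produces region-by-frame series directly from the same
latent process (voxel averaging emulated by scaling noise by 1/√n_voxels);
the volumetric and series paths share every downstream stage.

## What the generator does and does not emulate

Emulated: slowly rising constant-infusion time-activity curves with
network-structured fluctuations in the late frames; across-subject
covariance of summed uptake; autocorrelated BOLD-like series with the same
network structure; a patient-specific excess of cortical-motor edges; a
severity score monotonically coupled to motor-network strength.

Not emulated: pharmacokinetics (no compartment model), scanner physics,
attenuation, motion, spatial smoothing (irrelevant at ROI scale),
physiological noise spectra, spatial autocorrelation within parcels beyond
the shared regional signal, and realistic parcel geometry (parcels are
contiguous blocks in the flattened grid). Passing tests therefore
demonstrate the correctness of the estimators and the qualitative
recoverability of planted effects under idealized noise — not performance
on real imaging data. Dice coefficients and cross-modal associations run
higher than real multimodal studies report, because the same latent
communities drive every modality by construction.

## Degenerate inputs and tie-breaks

* Zero-variance series: r recorded as 0 with p = 1 and the region flagged
  (conservative, keeps matrices total). One-sample t with zero variance:
  p = 0 for nonzero mean, p = 1 for zero mean.
* r = ±1 duplicates: clipped before atanh so z stays finite.
* Both edge sets empty: DC = 0, flagged.
* A constant sample routes the normality-gated comparison to the rank test
  (Shapiro-Wilk is undefined there); two identical constant samples give
  statistic 0, p = 1. Setting `alpha_norm = 1` forces the rank path,
  `alpha_norm = 0` the t path.
* Mann-Whitney U follows the first-sample orientation (pairs with
  x > y); exact p when the combined n ≤ 20 without ties.
* The odds ratio is the conditional MLE under the noncentral
  hypergeometric model (via `fisher.test`); zero margins are an error,
  zero cells with nonzero margins yield a flagged boundary estimate.
* Unknown configuration keys are errors, never warnings — a typo must not
  silently fall back to a default.

## Problem sizes

Defaults keep every stage desk-sized: 30 regions × 1152 voxels, 25
subjects, ICA on ≤ 390 × 1152 matrices. The full volumetric pipeline runs
in seconds; the test suite's heaviest blocks are the five-seed parameter
recovery (five full pipeline runs) and a 200-replicate null simulation for
the type-I rate of the unit-degree Holm families, run in series mode.

## Known limitations

* Group ICA uses single-stage PCA reduction, not a two-stage subject-level
  reduction, and no back-reconstruction, dual regression, or
  stability/ICASSO analysis.
* No partial correlation, sparse inverse covariance, sliding-window
  dynamics, or graph metrics beyond degree.
* The conversion between region-level and voxel-level ICA inputs means the
  series-mode pipeline (no volumes) identifies the motor network reliably
  only via its unit-label fallback; volumetric mode is the primary path.
* Inputs must be pre-aligned; the NIfTI affine is carried through I/O but
  never used for resampling.
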