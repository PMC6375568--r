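---
title: "Methods: LV quantification, sport indices and cut-off diagnostics on synthetic phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LV quantification, sport indices and cut-off diagnostics on synthetic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmrsport)
```

## The problem and the two quantification models

Sustained intensive training remodels the left ventricle — larger cavity,
thicker wall — into a phenotype that can overlap with mild hypertrophic
cardiomyopathy (HCM). The discriminating observation is geometric: athletic
remodeling scales wall thickness *with* cavity volume, while HCM thickens
the wall *against* a normal or small cavity. The sport indices make this a
number: EDWT/LVEDVi (maximal end-diastolic wall thickness over
BSA-indexed end-diastolic volume, mm·m²/ml) and LVM/LVEDV (mass over
unindexed volume, g/ml). Both depend on how volumes and mass are
quantified, so the package implements the two image-analysis models whose
difference is itself diagnostic:

* **CQ (conventional, contour-based).** The endocardial contour is drawn
  around the smooth cavity boundary; everything inside it — blood *and*
  the trabeculae/papillary muscles (TPM) — counts as cavity. Volumes are
  slice sums `V = Σ Aᵢ (Δz + gap)` of polygon areas (shoelace formula);
  mass is the epi−endo annulus volume at end-diastole times
  ρ = 1.05 g/ml.
* **TQ (threshold-based).** Within the epicardial contour of each slice,
  blood and muscle intensities are estimated and each voxel is classified
  at the cut `μ_m + f (μ_b − μ_m)`, `f = 0.50`. Muscle voxels inside the
  endocardial contour are TPM: they move from the blood pool into mass.
  Consequently on any trabeculated ventricle `LVEDV_TQ < LVEDV_CQ`,
  `LVM_TQ > LVM_CQ` and `LVEF_TQ > LVEF_CQ`; these orderings are enforced
  as tests.

Assumptions worth stating: myocardial density is uniform (1.05 g/ml, the
standard CMR convention — not configurable per tissue class); every slice
bearing both contours contributes to the sums (the phantoms provide
unambiguous full coverage, so the basal-slice inclusion dilemma of clinical
stacks does not arise); on multi-phase input end-diastole is the phase of
maximal cavity volume and end-systole the minimal.

### Intensity estimation

"Spatially varying" blood/muscle estimation is realized per slice: the
in-mask intensity sample is split into two classes by maximizing the
between-class variance over cuts at midpoints of adjacent distinct values
(Otsu's criterion applied to the raw sample rather than a binned
histogram, which keeps the estimate exact on small masks). The class means
are the per-slice blood and muscle estimates. A slice whose in-mask
intensities have no spread cannot be split; it falls back to the pooled
whole-phase estimates and is recorded in `fallback_slices`, and only if
the pooled sample is also degenerate does the method error. Ties at the
threshold are labeled muscle — the conservative choice toward mass; the
alternative convention would shift TQ mass by at most the tied-voxel
volume, which is zero in continuous-noise data.

## Wall-thickness geometry

The myocardial centerline of a slice is sampled by rays from the cavity
centroid: each centerline point is the midpoint between the endocardial
and epicardial crossings of a ray, tangents come from central differences,
and thickness at a sample is the length of the compact-wall intersection
of the chord through the sample perpendicular to the tangent. The chord is
clipped to the *first* epicardial crossing outward and the nearest
endocardial crossing inward, so in strongly asymmetric shapes it cannot
traverse the opposite wall. Chords that miss a boundary are skipped and
counted; above 10% skipped the result carries a warning status. The
maximum is taken over all slices (the source protocol does not say whether
a slice is preselected; maximizing over all slices is the choice here),
and the minimum within that same slice, since max/min EDWT is a
within-slice asymmetry ratio. 360 chords per slice (1° spacing) put the
angular discretization error far below the voxel limit; thickness is
measured on contours only, so TPM never contribute to EDWT.

## The phantom generator

The phantom is the package's test instrument: a two-phase voxelized LV
with analytic ground truth, emulating the acquisition geometry of a
short-axis cine protocol (8 mm slices, no gap, ~1–2 mm in-plane).

* **Wall model.** Per-slice annulus with angular thickness
  `t(θ) = base + A·exp((cos(θ−θ₀)−1)/w²)` — a von Mises bump on a uniform
  ring. `A = 0` gives the symmetric athlete-like wall; `A > 0` emulates
  asymmetric basal-septal-type thickening, and the analytic maximum
  `base + A` is the reference for EDWT recovery. The same thickness
  function is used at both phases (systolic wall thickening is not
  modeled; mass is measured at end-diastole only, so this costs nothing).
* **TPM model.** Two papillary cylinders at ±60° from the bump center on
  the central 40% of slices, plus radial trabecular ridges occupying a
  configurable angular fraction (≤ 0.3) of a 3 mm band inside the
  endocardial surface. No published TPM geometry exists; these shapes were
  chosen for controllable mass and strict monotonicity (raising the
  trabecular fraction raises TPM volume and leaves compact mass
  unchanged — a property test).
* **Partial volume.** Classes are painted on a k× supersampled lattice
  (default k = 4) and block-averaged to the acquisition grid, producing
  the intermediate boundary intensities that exercise the 50% threshold.
  Ground truth is counted on the supersampled lattice, independent of the
  quantification code under test.
* **Noise.** Additive Gaussian on the averaged intensities. Magnitude MR
  images are Rician, but at the blood–muscle contrasts simulated here
  (SNR ≳ 10) the Rician distribution is near-Gaussian and no noise model
  is specified by the source protocol; default σ = 0, tests use σ up to
  25 on a contrast of 800.
* **Contours** are the analytic circles/epi curves (256 vertices), i.e.
  the observer is simulated as exact. Voxel membership is decided by the
  voxel-center-in-polygon test — deterministic and convergent under grid
  refinement.

What the phantom does *not* emulate: long-axis tapering of the ventricle
(slices are identical up to papillary placement), through-plane motion,
surface coils and intensity shading, the right ventricle, and manual
contouring error. Recovery tests on phantoms therefore validate the
*computational* chain — rasterization, thresholding, partitioning,
geometry — not robustness to anatomical variation or observer variability.

## The cohort simulator

`sample_cohort()` draws subjects from the four published groups
(male/female × athlete/HCM, n = 101/108/49/86) as independent Gaussians
per index with the printed mean ± SD, resampling non-positive draws. Only
marginal statistics are published, so no correlation structure is imposed;
joint-distribution quantities — most notably the exact published AUCs
(0.998/0.999) — are *not* reproducible from marginals, and the cohort
tests assert the reproducible structure instead: group means within
sampling error of their targets and the published ordering of
discriminative performance (EDWT/LVEDVi under either method beats max/min
EDWT).

## ROC and cut-off conventions

Candidate thresholds are the midpoints between adjacent distinct observed
values with ∓∞ sentinels, classification is by strict `>`, AUC is the
trapezoidal area (equal to the Mann–Whitney statistic with half-credit
ties — asserted against a brute-force all-pairs oracle), and the reported
cut-off maximizes the proportion correctly classified with ties broken
toward the smaller threshold (the more sensitive choice). Metrics with a
zero denominator are undefined (`NA`), never zero. Paired AUCs are
compared with DeLong's structural-components test, the field standard for
correlated ROC curves (the source analysis names no test); its variance is
cross-checked against both an independent implementation and a bootstrap.
Group comparisons use least-squares regression of the outcome on a group
indicator plus age and heart rate within strata, matching the published
adjustment; median regression for non-normal outcomes is out of scope, so
heavy-tailed outcomes rely on least-squares robustness at these group
sizes. Classification cut-offs are strict (`>`), so a value exactly at a
published cut-off falls to the athlete range, and the hypertrophy grey
zone is the inclusive band 13 ≤ EDWT ≤ 16 mm (the source writes "13–16 mm"
without bracket semantics).

## Problem sizes and numerical tolerances

The test suite runs phantoms at 2 mm in-plane spacing with 2× supersampling
for fast property checks, and 1 mm with 4× supersampling (the resolution
regime of clinical cine CMR) for ground-truth recovery: volumes and masses
recover within 2%, TPM mass within 5%, and measured maximal EDWT within
one voxel diagonal of the analytic value; volume errors shrink
monotonically over 2 → 1 → 0.5 mm. At 2 mm, trabecular ridges (~0.6 mm
arc width) are sub-voxel and alias into the blood pool — a real
partial-volume phenomenon, and the reason the recovery and ordering checks
are stated at 1 mm. Cohort-level checks use the full published group sizes
(344 subjects). The one tunable numerical guard worth knowing: polygon
edge crossings use a 10⁻⁹ half-open parameter window so a ray through a
polygon vertex is counted on exactly one adjacent edge.

## Known limitations

* The simulated observer is perfect; contour-placement variability, the
  dominant error source in practice, is absent.
* Cohort simulation cannot reproduce joint-distribution diagnostics (see
  above); published AUC/sensitivity/specificity values are reference
  points, not targets the simulation can hit.
* The phantom is a stack of identical annuli; apical morphology (and so
  apical-HCM-like shapes) is not modeled.
* Late gadolinium enhancement is handled only at the level of its
  published contingency counts; no enhancement images are synthesized.
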