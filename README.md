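# cmrsport

Differentiating athlete's heart from hypertrophic cardiomyopathy (HCM) on
cardiac MR is hardest in the *grey zone* of hypertrophy — maximal
end-diastolic wall thickness (EDWT) between 13 and 16 mm — where intense
training and mild disease produce overlapping phenotypes. `cmrsport`
implements the CMR "sport index" approach to this problem as a fully tested
R pipeline: two left-ventricular quantification methods, wall-thickness
geometry, body-surface-area indexing, sport-index computation, and ROC
cut-off diagnostics, exercised entirely on synthetic LV phantoms and
simulated cohorts so that every stage is verifiable without patient data.

## What it computes

**Two quantification methods on the same short-axis cine stack.**

* *Conventional quantification (CQ)*: cavity volumes by slice summation of
  the endocardial contour areas, `V = Σ Aᵢ·(Δz + gap)`, so trabeculae and
  papillary muscles (TPM) are counted in the blood pool; myocardial mass
  from the epi−endo annulus at end-diastole, `LVM = ρ·V_myo` with
  ρ = 1.05 g/ml.
* *Threshold-based quantification (TQ)*: per slice, blood and muscle signal
  intensities are estimated inside the epicardial contour (two-class
  maximal between-class-variance split) and every voxel is classified at
  the cut `μ_muscle + f·(μ_blood − μ_muscle)` with f = 0.50 invariably;
  muscle voxels inside the endocardial contour are TPM and count toward
  mass, not the blood pool.

**Wall geometry.** EDWT is measured per slice along chords perpendicular to
the myocardial centerline (the mid-wall curve between contours); the
maximum is taken over all slices, the minimum within the slice holding the
maximum, giving the max/min EDWT asymmetry ratio.

**Sport indices.** `EDWT/LVEDVi` (mm·m²/ml), `LVM/LVEDV` (g/ml) — each
under both methods — and `TPM% = 100·TPM/LVM_TQ`. Volumes and masses are
indexed to Du Bois body surface area
`BSA = 0.007184·h^0.725·w^0.425`.

**Diagnostics.** ROC curves (trapezoidal AUC = Mann–Whitney concordance
with half-credit ties), cut-offs chosen to maximize the proportion of
subjects correctly classified (a value strictly above the cut-off is in the
HCM range), sensitivity/specificity/PPV/NPV, DeLong's paired AUC
comparison, and least-squares group comparisons adjusted for age and heart
rate.

**Synthetic data.** `generate_phantom()` builds a two-phase voxelized LV —
bright blood pool, darker compact wall with a von Mises thickness bump
(asymmetric septal-type thickening), trabecular ridges and papillary
cylinders, partial volume via supersampled averaging, Gaussian noise — with
analytic ground truth. `sample_cohort()` draws index-level cohorts from the
published four-group statistics (male/female × athlete/HCM, n =
101/108/49/86).

## Worked example

An athlete-like phantom (endocardial radius 25 mm at end-diastole, uniform
8 mm wall, papillary muscles and 15% trabeculation, noise σ = 20):

```r
library(cmrsport)
spec <- phantom_spec(endo_radius_ed = 25, endo_radius_es = 18, wall_base = 8,
                     n_papillary = 2, trabecular_fraction = 0.15,
                     noise_sigma = 20, seed = 7)
ph <- generate_phantom(spec)
cq <- cq_quantify(ph$stack, ph$contours)
tq <- tq_quantify(ph$stack, ph$contours)
w  <- measure_edwt(ph$contours$ED)
si <- compute_sport_indices(w, cq, tq, bsa = compute_bsa(185, 85))
classify_subject(si)$labels
```

```
LV volumetrics (CQ method)
  LVEDV 157.1 ml  LVESV 81.4 ml  LVSV 75.6 ml  LVEF 48.2%
  LVM 122.4 g
LV volumetrics (TQ method)
  LVEDV 149.5 ml  LVESV 74.5 ml  LVSV 75.0 ml  LVEF 50.2%
  LVM 131.7 g  TPM 9.1 g
EDWT: max 8.0 mm (slice 1), min 8.0 mm, max/min 1.00 [ok]
                        index threshold     value         label
edwt_lvedvi_cq edwt_lvedvi_cq      0.14 0.1064345 athlete-range
lvm_lvedv_cq     lvm_lvedv_cq      0.82 0.7795200 athlete-range
edwt_lvedvi_tq edwt_lvedvi_tq      0.17 0.1118525 athlete-range
lvm_lvedv_tq     lvm_lvedv_tq      1.27 0.8811637 athlete-range
maxmin_edwt       maxmin_edwt      2.40 1.0000752 athlete-range
```

Reading the output: TQ moves ~9 g of TPM from the blood pool into mass, so
its cavity volumes are smaller, its mass larger and its ejection fraction
higher than CQ on the same images — the systematic between-method offset
that motivates method-specific cut-offs. All five indices fall below their
HCM cut-offs, so every rule labels this subject athlete-range, and with a
maximal EDWT of 8 mm it is outside the 13–16 mm grey zone.

`run_pipeline()` composes these stages over a subject list and writes
`indices.csv`, per-index ROC reports and a cut-off summary table; a thin
command-line front end with subcommands `phantom`, `cohort`, `quantify`,
`edwt`, `roc`, `compare-auc` and `run` lives at `inst/cli/cmrsport.R`.

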