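Package: cmrsport
Title: Sport Indices from Cardiac MR Quantification to Separate Athlete's Heart from Hypertrophic Cardiomyopathy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for left-ventricular quantification of short-axis cine
    cardiac MR stacks by two methods (conventional contour-based and
    threshold-based voxel classification with a 50% blood-muscle intensity
    threshold), wall-thickness geometry along the myocardial centerline,
    body-surface-area indexing, sport-index computation (EDWT/LVEDVi,
    LVM/LVEDV, TPM%), and ROC cut-off diagnostics for distinguishing
    physiological from pathological hypertrophy. Includes a synthetic
    left-ventricular phantom generator with analytic ground truth and a
    cohort simulator parameterized by published group statistics, so the
    full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite, RNifti
Suggests: testthat (>= 3.0.0), pROC, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
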