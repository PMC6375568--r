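# Published group statistics used as simulator defaults and as reference
# inputs. Values are the printed means/SDs and counts from the source
# cohorts: elite athletes vs hypertrophic cardiomyopathy (HCM) patients,
# split by sex, plus the small athletes-with-HCM group.

#' Reference group statistics for the four sex-by-diagnosis cohorts
#'
#' Printed mean and SD per sport index for male/female athletes and
#' male/female HCM patients, with group sizes (101/108/49/86). These are the
#' default parameters of [cohort_spec()].
#'
#' Index names: `edwt` (mm), `maxmin_edwt` (dimensionless),
#' `edwt_lvedvi_cq`/`edwt_lvedvi_tq` (mm·m²/ml),
#' `lvm_lvedv_cq`/`lvm_lvedv_tq` (g/ml), `tpm_pct` (%).
#'
#' @return Data frame with columns `group`, `sex`, `diagnosis`, `n`,
#'   `index`, `mean`, `sd`.
#' @export
reference_group_stats <- function() {
  idx <- c("edwt", "maxmin_edwt", "edwt_lvedvi_cq", "lvm_lvedv_cq",
           "edwt_lvedvi_tq", "lvm_lvedv_tq", "tpm_pct")
  g <- data.frame(
    group = rep(c("male_athlete", "male_hcm", "female_athlete", "female_hcm"),
                each = length(idx)),
    sex = rep(c("M", "M", "F", "F"), each = length(idx)),
    diagnosis = rep(c("athlete", "HCM", "athlete", "HCM"), each = length(idx)),
    n = rep(c(101L, 108L, 49L, 86L), each = length(idx)),
    index = rep(idx, times = 4L),
    mean = c(12.6, 1.93, 0.10, 0.75, 0.13, 1.13, 19.0,
             22.1, 3.56, 0.25, 1.08, 0.34, 1.93, 22.1,
             10.4, 2.17, 0.10, 0.62, 0.12, 0.95, 21.1,
             19.7, 3.86, 0.25, 0.97, 0.36, 1.83, 23.1),
    sd = c(1.3, 0.30, 0.02, 0.13, 0.02, 0.16, 3.7,
           5.4, 1.53, 0.08, 0.30, 0.10, 0.60, 4.6,
           1.2, 0.45, 0.02, 0.10, 0.02, 0.14, 4.7,
           5.2, 1.63, 0.07, 0.25, 0.12, 0.56, 4.1),
    stringsAsFactors = FALSE
  )
  g
}

#' Reference volumetrics of the athletes-with-HCM group
#'
#' Printed mean ± SD of the BSA-indexed left-ventricular parameters of the
#' ten athletes with HCM, under both quantification methods. Useful as
#' generator targets and for printed-table identity checks
#' (e.g. LVSVi = LVEDVi − LVESVi under the threshold-based method).
#'
#' @return Data frame with columns `parameter`, `method`, `mean`, `sd`.
#' @export
reference_athlete_hcm <- function() {
  data.frame(
    parameter = c("edwt", "maxmin_edwt",
                  "lvef", "lvesvi", "lvedvi", "lvsvi", "lvmi",
                  "edwt_lvedvi", "lvm_lvedv",
                  "lvef", "lvesvi", "lvedvi", "lvsvi", "lvmi",
                  "edwt_lvedvi", "lvm_lvedv", "tpm", "tpmi", "tpm_pct"),
    method = c(NA, NA, rep("CQ", 7L), rep("TQ", 10L)),
    mean = c(17.7, 2.28,
             63.3, 37.3, 101.3, 64.1, 94.8, 0.18, 0.94,
             72.3, 21.1, 75.8, 54.7, 121.3, 0.24, 1.62, 41.1, 21.4, 17.4),
    sd = c(2.7, 0.52,
           4.2, 5.1, 7.8, 6.5, 15.0, 0.03, 0.13,
           4.6, 4.3, 7.7, 6.1, 16.9, 0.05, 0.28, 12.6, 6.3, 4.4),
    stringsAsFactors = FALSE
  )
}

#' Published cut-off rules for the sport indices
#'
#' The reported accuracy-maximizing cut-offs: an index value strictly above
#' its threshold is in the HCM range. Returned as a [cutoff_rules()] object
#' usable directly by [classify_subject()].
#'
#' @return A `cutoff_rules` object with the five published rules.
#' @export
reference_cutoff_rules <- function() {
  cutoff_rules(
    index = c("edwt_lvedvi_cq", "lvm_lvedv_cq",
              "edwt_lvedvi_tq", "lvm_lvedv_tq", "maxmin_edwt"),
    method = c("CQ", "CQ", "TQ", "TQ", NA),
    threshold = c(0.14, 0.82, 0.17, 1.27, 2.4)
  )
}
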