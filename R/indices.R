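# Body-surface-area indexing, sport indices and cut-off classification.
# The sport indices are ratios designed to separate physiological from
# pathological hypertrophy: EDWT/LVEDVi (mm·m²/ml), LVM/LVEDV (g/ml, both
# unindexed), TPM% (TPM mass as a percentage of threshold-based LVM), and
# the within-slice max/min EDWT ratio.

GREY_ZONE_MM <- c(13, 16)   # inclusive borderline-hypertrophy band, mm

#' Body surface area (Du Bois)
#'
#' `BSA = 0.007184 * height^0.725 * weight^0.425` with height in cm and
#' weight in kg.
#'
#' @param height_cm height, cm.
#' @param weight_kg weight, kg.
#' @return BSA in m². Vectorized.
#' @examples
#' compute_bsa(180, 80)
#' @export
compute_bsa <- function(height_cm, weight_kg) {
  check_positive(height_cm, "height_cm")
  check_positive(weight_kg, "weight_kg")
  0.007184 * height_cm^0.725 * weight_kg^0.425
}

#' Index a volume or mass to body surface area
#'
#' @param value volume (ml) or mass (g).
#' @param bsa body surface area, m².
#' @return `value / bsa`.
#' @export
index_to_bsa <- function(value, bsa) {
  check_positive(bsa, "bsa")
  value / bsa
}

#' Compute the sport indices for one subject
#'
#' `edwt_lvedvi_*` = max EDWT / (LVEDV/BSA); `lvm_lvedv_*` = LVM / LVEDV
#' (both unindexed); `tpm_pct` = 100 * TPM / LVM under the threshold-based
#' method; `maxmin_edwt` from the wall-thickness result.
#'
#' @param wall an [measure_edwt()] result.
#' @param vol_cq,vol_tq `lv_volumetrics` from [cq_quantify()] /
#'   [tq_quantify()]; either may be `NULL` to skip that method's indices,
#'   but `tpm` requires the TQ result.
#' @param bsa body surface area, m² (e.g. from [compute_bsa()]).
#' @param tpm whether to compute `tpm_pct` (default: when TQ is present).
#' @return A `sport_indices` object (named list of index values).
#' @export
compute_sport_indices <- function(wall, vol_cq = NULL, vol_tq = NULL, bsa,
                                  tpm = !is.null(vol_tq)) {
  check_positive(bsa, "bsa")
  if (is.null(vol_cq) && is.null(vol_tq))
    stop_cmr("at least one quantification result is required")
  if (tpm && is.null(vol_tq))
    stop_cmr("tpm_pct requires the threshold-based (TQ) result")
  out <- list(max_edwt = wall$max_edwt, maxmin_edwt = wall$max_min_ratio)
  for (m in c("cq", "tq")) {
    v <- if (m == "cq") vol_cq else vol_tq
    if (is.null(v)) next
    out[[paste0("edwt_lvedvi_", m)]] <- wall$max_edwt / index_to_bsa(v$LVEDV, bsa)
    out[[paste0("lvm_lvedv_", m)]] <- v$LVM / v$LVEDV
  }
  if (tpm) out$tpm_pct <- 100 * vol_tq$TPM / vol_tq$LVM
  structure(out, class = "sport_indices")
}

#' Cut-off rules for index-based classification
#'
#' Each rule compares one index against a threshold: a value strictly above
#' the threshold is in the HCM range, at or below it in the athlete range.
#'
#' @param index character vector of index names (e.g. `"edwt_lvedvi_cq"`).
#' @param threshold numeric thresholds.
#' @param method optional method tag per rule (`"CQ"`, `"TQ"` or `NA`).
#' @return A `cutoff_rules` data frame.
#' @seealso [reference_cutoff_rules()] for the published defaults.
#' @export
cutoff_rules <- function(index, threshold, method = NA_character_) {
  if (length(index) != length(threshold))
    stop_cmr("'index' and 'threshold' lengths differ")
  if (any(!is.finite(threshold))) stop_cmr("thresholds must be finite")
  structure(data.frame(index = as.character(index),
                       method = rep_len(method, length(index)),
                       threshold = threshold, stringsAsFactors = FALSE),
            class = c("cutoff_rules", "data.frame"))
}

#' Classify a subject against cut-off rules
#'
#' Applies each rule by strict comparison (`value > threshold` implies the
#' HCM range) and flags the hypertrophy grey zone (max EDWT in the inclusive
#' 13-16 mm band) when a `max_edwt` entry is present.
#'
#' @param indices a `sport_indices` object or named list/vector of index
#'   values.
#' @param rules a [cutoff_rules()] set.
#' @return List with `labels` (data frame: index, threshold, value, label)
#'   and `grey_zone` (logical, `NA` when max EDWT is unknown).
#' @export
classify_subject <- function(indices, rules = reference_cutoff_rules()) {
  vals <- unlist(indices)
  missing <- setdiff(rules$index, names(vals))
  if (length(missing))
    stop_cmr("unknown index in rules: %s", paste(missing, collapse = ", "))
  v <- vals[rules$index]
  labels <- data.frame(index = rules$index, threshold = rules$threshold,
                       value = unname(v),
                       label = ifelse(v > rules$threshold,
                                      "HCM-range", "athlete-range"),
                       stringsAsFactors = FALSE)
  grey <- if ("max_edwt" %in% names(vals))
    vals[["max_edwt"]] >= GREY_ZONE_MM[1L] &
      vals[["max_edwt"]] <= GREY_ZONE_MM[2L] else NA
  list(labels = labels, grey_zone = grey)
}
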