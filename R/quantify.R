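# Left-ventricular quantification by two methods on the same short-axis
# stack:
#   CQ (conventional, contour-based): cavity volume from endocardial polygon
#     areas, so trabeculae and papillary muscles (TPM) are counted in the
#     blood pool; mass from the epi-endo annulus at end-diastole.
#   TQ (threshold-based): every voxel inside the epicardial contour is
#     classified blood or muscle at a cut placed a fixed fraction (default
#     50%) of the way from the muscle to the blood intensity estimate;
#     muscle voxels inside the endocardial contour are TPM and count toward
#     mass, not the blood pool.

MYOCARDIAL_DENSITY <- 1.05  # g/ml, standard CMR convention

#' Slice-summation volume
#'
#' Simpson-style slice summation: each slice contributes its area times the
#' slab height (slice thickness + interslice gap).
#'
#' @param areas_mm2 per-slice areas, mm^2 (may be empty).
#' @param slice_thickness slice thickness, mm.
#' @param slice_gap interslice gap, mm (default 0).
#' @return Volume in ml.
#' @examples
#' slice_summation_volume(1000, 8)  # 8 ml
#' @export
slice_summation_volume <- function(areas_mm2, slice_thickness, slice_gap = 0) {
  check_positive(slice_thickness, "slice_thickness")
  if (slice_gap < 0) stop_cmr("'slice_gap' must be >= 0")
  if (length(areas_mm2) == 0L) return(0)
  if (any(!is.finite(areas_mm2)) || any(areas_mm2 < 0))
    stop_cmr("slice areas must be finite and >= 0")
  mm3_to_ml(sum(areas_mm2) * (slice_thickness + slice_gap))
}

volumetric_result <- function(method, lvedv, lvesv, lvm, tpm = NA_real_,
                              slice_areas = NULL) {
  if (any(c(lvedv, lvesv, lvm) < 0)) stop_cmr("volumes and mass must be >= 0")
  structure(list(method = method, LVEDV = lvedv, LVESV = lvesv,
                 LVSV = lvedv - lvesv,
                 LVEF = if (lvedv > 0) 100 * (lvedv - lvesv) / lvedv else NA_real_,
                 LVM = lvm, TPM = tpm, slice_areas_cm2 = slice_areas),
            class = "lv_volumetrics")
}

#' @export
print.lv_volumetrics <- function(x, ...) {
  cat(sprintf("LV volumetrics (%s method)\n", x$method))
  cat(sprintf("  LVEDV %.1f ml  LVESV %.1f ml  LVSV %.1f ml  LVEF %.1f%%\n",
              x$LVEDV, x$LVESV, x$LVSV, x$LVEF))
  cat(sprintf("  LVM %.1f g", x$LVM))
  if (is.finite(x$TPM)) cat(sprintf("  TPM %.1f g", x$TPM))
  cat("\n")
  invisible(x)
}

phase_contours <- function(contours, phase) {
  if (!phase %in% names(contours))
    stop_cmr("contour set has no '%s' phase", phase)
  contours[[phase]]
}

#' Conventional (contour-based) quantification
#'
#' Cavity volumes from the endocardial polygon areas (slice summation), so
#' TPM are counted in the blood pool; myocardial mass from the epicardial
#' minus endocardial area at end-diastole times density. End-diastole is the
#' phase with the larger cavity volume.
#'
#' @param stack a `sax_stack` (supplies slice thickness and gap).
#' @param contours a `contour_set` with endo and epi polygons on every slice
#'   of both phases.
#' @param density myocardial density, g/ml.
#' @return An `lv_volumetrics` object, method `"CQ"`.
#' @export
cq_quantify <- function(stack, contours, density = MYOCARDIAL_DENSITY) {
  check_positive(density, "density")
  vols <- list(); masses <- list(); areas <- list()
  for (ph in names(contours)) {
    sl <- contours[[ph]]
    endo_a <- epi_a <- numeric(length(sl))
    for (s in seq_along(sl)) {
      if (is.null(sl[[s]]$endo))
        stop_cmr("CQ requires an endocardial contour on every slice (phase %s, slice %d)",
                 ph, s)
      endo_a[s] <- polygon_area(sl[[s]]$endo)
      epi_a[s] <- polygon_area(sl[[s]]$epi)
      if (epi_a[s] <= endo_a[s])
        stop_cmr("epicardial contour must enclose the endocardial contour (phase %s, slice %d)",
                 ph, s)
    }
    vols[[ph]] <- slice_summation_volume(endo_a, stack$slice_thickness,
                                         stack$slice_gap)
    masses[[ph]] <- slice_summation_volume(epi_a - endo_a,
                                           stack$slice_thickness,
                                           stack$slice_gap) * density
    areas[[ph]] <- endo_a / 100
  }
  ed <- names(vols)[which.max(unlist(vols))]
  es <- names(vols)[which.min(unlist(vols))]
  volumetric_result("CQ", vols[[ed]], vols[[es]], masses[[ed]],
                    slice_areas = areas)
}

#' Estimate per-slice blood and muscle intensities
#'
#' Two-class split of the intensities inside the epicardial mask of one
#' slice, by maximal between-class variance (Otsu's criterion on the raw
#' intensity sample). The class means are the blood (high) and muscle (low)
#' estimates.
#'
#' @param slice_img intensity matrix of one slice.
#' @param mask logical matrix, `TRUE` inside the epicardial contour.
#' @return List with `blood`, `muscle`, and `degenerate` (TRUE when the
#'   in-mask histogram has no spread to split).
#' @export
estimate_class_intensities <- function(slice_img, mask) {
  if (!any(mask)) stop_cmr("empty epicardial mask")
  sp <- otsu_split(slice_img[mask])
  list(blood = sp$high, muscle = sp$low, degenerate = sp$degenerate)
}

# logical epicardial / endocardial masks for one slice
contour_masks <- function(slice_contours, grid_dim, spacing) {
  cx <- (seq_len(grid_dim[1L]) - 0.5) * spacing
  cy <- (seq_len(grid_dim[2L]) - 0.5) * spacing
  px <- rep(cx, times = grid_dim[2L])
  py <- rep(cy, each = grid_dim[1L])
  epi <- matrix(points_in_polygon(px, py, slice_contours$epi),
                grid_dim[1L], grid_dim[2L])
  endo <- if (!is.null(slice_contours$endo))
    matrix(points_in_polygon(px, py, slice_contours$endo),
           grid_dim[1L], grid_dim[2L]) else NULL
  list(epi = epi, endo = endo)
}

#' Threshold-based voxel classification of one phase
#'
#' Labels every voxel inside the epicardial contour of each slice as blood
#' or muscle. The cut for a slice is
#' `muscle + threshold_fraction * (blood - muscle)` using that slice's
#' intensity estimates; voxels strictly above the cut are blood, ties and
#' voxels below are muscle. Muscle voxels strictly inside the endocardial
#' contour form the TPM partition. Slices whose histogram cannot be split
#' fall back to pooled whole-phase estimates (recorded in `fallback_slices`).
#'
#' @param phase_img 3-D intensity array (x, y, slice) of one phase.
#' @param slice_contours list per slice with `endo` and `epi` polygons.
#' @param in_plane_spacing in-plane voxel spacing, mm.
#' @param threshold_fraction fraction in (0, 1]; default 0.5.
#' @return A `label_map`: per-slice class matrices (0 outside, 1 cavity
#'   blood, 2 compact myocardium, 3 TPM) plus voxel counts.
#' @export
threshold_labelmap <- function(phase_img, slice_contours, in_plane_spacing,
                               threshold_fraction = 0.5) {
  if (threshold_fraction <= 0 || threshold_fraction > 1)
    stop_cmr("'threshold_fraction' must be in (0, 1]")
  n_slices <- dim(phase_img)[3L]
  if (length(slice_contours) != n_slices)
    stop_cmr("contour list length (%d) does not match slice count (%d)",
             length(slice_contours), n_slices)
  masks <- vector("list", n_slices)
  est <- vector("list", n_slices)
  pooled <- numeric(0)
  for (s in seq_len(n_slices)) {
    masks[[s]] <- contour_masks(slice_contours[[s]], dim(phase_img)[1:2],
                                in_plane_spacing)
    est[[s]] <- estimate_class_intensities(phase_img[, , s], masks[[s]]$epi)
    pooled <- c(pooled, phase_img[, , s][masks[[s]]$epi])
  }
  fallback <- which(vapply(est, function(e) isTRUE(e$degenerate), logical(1)))
  if (length(fallback)) {
    gl <- otsu_split(pooled)
    if (gl$degenerate)
      stop_cmr("degenerate intensity histogram: cannot separate blood from muscle")
    for (s in fallback) est[[s]] <- list(blood = gl$high, muscle = gl$low)
  }
  labels <- vector("list", n_slices)
  counts <- c(cavity_blood = 0L, compact = 0L, tpm = 0L)
  for (s in seq_len(n_slices)) {
    cut <- est[[s]]$muscle +
      threshold_fraction * (est[[s]]$blood - est[[s]]$muscle)
    lab <- matrix(0L, dim(phase_img)[1L], dim(phase_img)[2L])
    in_epi <- masks[[s]]$epi
    blood <- in_epi & phase_img[, , s] > cut        # ties fall to muscle
    muscle <- in_epi & !blood
    lab[blood] <- 1L
    lab[muscle] <- 2L
    if (!is.null(masks[[s]]$endo)) {
      tpm <- muscle & masks[[s]]$endo
      lab[tpm] <- 3L
    }
    labels[[s]] <- lab
    counts <- counts + c(cavity_blood = sum(lab == 1L),
                         compact = sum(lab == 2L), tpm = sum(lab == 3L))
  }
  structure(list(labels = labels, counts = counts,
                 fallback_slices = fallback,
                 threshold_fraction = threshold_fraction,
                 estimates = est), class = "label_map")
}

#' Threshold-based (TQ) quantification
#'
#' Cavity volumes are the blood-labeled voxel volumes per phase; myocardial
#' mass is all muscle-labeled voxel volume (compact wall plus TPM) at
#' end-diastole times density, with the TPM mass also reported separately.
#'
#' @inheritParams cq_quantify
#' @param threshold_fraction blood-muscle threshold fraction, default 0.5.
#' @return An `lv_volumetrics` object, method `"TQ"`, with `TPM` mass set.
#' @export
tq_quantify <- function(stack, contours, threshold_fraction = 0.5,
                        density = MYOCARDIAL_DENSITY) {
  check_positive(density, "density")
  voxvol <- stack$in_plane_spacing^2 *
    (stack$slice_thickness + stack$slice_gap)     # mm^3
  maps <- list(); cavity <- list(); areas <- list()
  for (ph in names(contours)) {
    maps[[ph]] <- threshold_labelmap(stack$phases[[ph]], contours[[ph]],
                                     stack$in_plane_spacing,
                                     threshold_fraction)
    cavity[[ph]] <- mm3_to_ml(maps[[ph]]$counts[["cavity_blood"]] * voxvol)
    areas[[ph]] <- vapply(maps[[ph]]$labels, function(l)
      sum(l == 1L) * stack$in_plane_spacing^2 / 100, numeric(1))
  }
  ed <- names(cavity)[which.max(unlist(cavity))]
  es <- names(cavity)[which.min(unlist(cavity))]
  myo_ml <- mm3_to_ml((maps[[ed]]$counts[["compact"]] +
                         maps[[ed]]$counts[["tpm"]]) * voxvol)
  tpm_ml <- mm3_to_ml(maps[[ed]]$counts[["tpm"]] * voxvol)
  res <- volumetric_result("TQ", cavity[[ed]], cavity[[es]],
                           myo_ml * density, tpm = tpm_ml * density,
                           slice_areas = areas)
  res$label_maps <- maps
  res
}
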