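# Interchange formats: NIfTI image stacks (one file per cardiac phase, mm
# voxel spacing in the header, phase labels in a JSON sidecar), contour
# polygons as JSON, results as JSON/CSV. Plus the end-to-end pipeline
# driver.

#' Write a short-axis stack as NIfTI
#'
#' One NIfTI file per phase (`<prefix>_<phase>.nii`) with mm spacing in the
#' header, and a `<prefix>.json` sidecar recording phase labels and slice
#' geometry.
#'
#' @param stack a `sax_stack`.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return Invisibly, the sidecar path.
#' @export
write_stack <- function(stack, dir, prefix = "stack") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dz <- stack$slice_thickness + stack$slice_gap
  files <- character(0)
  for (ph in names(stack$phases)) {
    img <- RNifti::asNifti(stack$phases[[ph]])
    RNifti::pixdim(img) <- c(stack$in_plane_spacing, stack$in_plane_spacing,
                             dz)
    f <- file.path(dir, sprintf("%s_%s.nii", prefix, ph))
    RNifti::writeNifti(img, f)
    files[ph] <- basename(f)
  }
  sidecar <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(list(phases = as.list(files),
                            in_plane_spacing = stack$in_plane_spacing,
                            slice_thickness = stack$slice_thickness,
                            slice_gap = stack$slice_gap),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a short-axis stack written by [write_stack()]
#'
#' @param sidecar path to the `<prefix>.json` sidecar.
#' @return A `sax_stack`.
#' @export
read_stack <- function(sidecar) {
  meta <- tryCatch(jsonlite::read_json(sidecar),
                   error = function(e) stop_cmr("unreadable sidecar: %s",
                                                conditionMessage(e)))
  for (f in c("phases", "in_plane_spacing", "slice_thickness", "slice_gap"))
    if (is.null(meta[[f]])) stop_cmr("sidecar missing field '%s'", f)
  dir <- dirname(sidecar)
  phases <- lapply(meta$phases, function(f) {
    img <- tryCatch(suppressWarnings(RNifti::readNifti(file.path(dir, f))),
                    error = function(e)
                      stop_cmr("unreadable NIfTI '%s': %s", f,
                               conditionMessage(e)))
    pd <- RNifti::pixdim(img)
    if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
      stop_cmr("NIfTI '%s' lacks positive mm spacing metadata", f)
    if (abs(pd[1L] - meta$in_plane_spacing) > 1e-6)
      stop_cmr("NIfTI '%s' spacing disagrees with sidecar", f)
    array(as.numeric(img), dim = dim(img))
  })
  structure(list(phases = phases,
                 in_plane_spacing = meta$in_plane_spacing,
                 slice_thickness = meta$slice_thickness,
                 slice_gap = meta$slice_gap), class = "sax_stack")
}

#' Write a contour set as JSON
#'
#' Flat array of records `{phase, slice_index, role, polygon}` with closed
#' polygons in planar mm coordinates (origin at the grid corner).
#'
#' @param contours a `contour_set`.
#' @param path output path.
#' @export
write_contours <- function(contours, path) {
  recs <- list()
  for (ph in names(contours)) {
    for (s in seq_along(contours[[ph]])) {
      for (role in c("endo", "epi")) {
        poly <- contours[[ph]][[s]][[role]]
        if (is.null(poly)) next
        closed <- rbind(poly, poly[1L, ])
        recs[[length(recs) + 1L]] <-
          list(phase = ph, slice_index = s, role = role,
               polygon = unname(apply(closed, 1L, as.list)))
      }
    }
  }
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a contour set written by [write_contours()]
#'
#' @param path JSON path.
#' @return A `contour_set`.
#' @export
read_contours <- function(path) {
  recs <- tryCatch(jsonlite::read_json(path),
                   error = function(e) stop_cmr("unreadable contour JSON: %s",
                                                conditionMessage(e)))
  out <- list()
  for (r in recs) {
    if (is.null(r$phase) || is.null(r$slice_index) || is.null(r$role) ||
        is.null(r$polygon))
      stop_cmr("contour record missing a required field")
    poly <- do.call(rbind, lapply(r$polygon, function(p)
      c(p[[1L]], p[[2L]])))
    ph <- r$phase; s <- as.integer(r$slice_index)
    if (is.null(out[[ph]])) out[[ph]] <- list()
    while (length(out[[ph]]) < s)
      out[[ph]][[length(out[[ph]]) + 1L]] <- list(endo = NULL, epi = NULL)
    out[[ph]][[s]][[r$role]] <- as_polygon(poly)
  }
  structure(out, class = "contour_set")
}

# tiny polynomial rolling hash of a character scalar, for provenance
# stamping (not cryptographic)
config_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

default_subject_phantoms <- list(
  athlete = list(endo_radius_ed = 25, endo_radius_es = 18, wall_base = 8,
                 wall_bump_amplitude = 0, n_papillary = 2,
                 trabecular_fraction = 0.15),
  hcm = list(endo_radius_ed = 20, endo_radius_es = 15, wall_base = 8,
             wall_bump_amplitude = 14, n_papillary = 2,
             trabecular_fraction = 0.2)
)

#' Run the full phantom-to-diagnostics pipeline
#'
#' For every subject, generates its LV phantom, quantifies it with both
#' methods, measures wall thickness, computes BSA-indexed sport indices and
#' classifies them against the cut-off rules; when both diagnoses are
#' present, fits a ROC with accuracy-maximizing cut-off per rule index.
#' Writes `indices.csv`, `roc.json`, `cutoff_table.csv` and
#' `provenance.json` (config hash, seed, package version) to the output
#' directory. Deterministic given the seed.
#'
#' @param config list with `subjects` (list of subject lists: `id`, `sex`,
#'   `group` ("athlete"/"HCM"/"athlete-HCM"), `age`, `height`, `weight`,
#'   `heart_rate`, and optionally `phantom`, a list of [phantom_spec()]
#'   overrides; without one, a default athlete-like or HCM-like phantom is
#'   used by group), `out_dir`, `seed`, and optional `density`,
#'   `threshold_fraction`, `rules` (a [cutoff_rules()] set).
#' @return Invisibly, a list with the indices data frame and per-index ROC
#'   reports.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$subjects) || !length(config$subjects))
    stop_cmr("config has an empty subject list")
  if (is.null(config$out_dir)) stop_cmr("config needs 'out_dir'")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  density <- if (is.null(config$density)) MYOCARDIAL_DENSITY else config$density
  thr <- if (is.null(config$threshold_fraction)) 0.5 else
    config$threshold_fraction
  rules <- if (is.null(config$rules)) reference_cutoff_rules() else
    config$rules
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)

  stage <- function(name, id, expr) {
    tryCatch(expr, error = function(e)
      stop_cmr("pipeline stage '%s' failed for subject '%s': %s",
               name, id, conditionMessage(e)))
  }
  rows <- vector("list", length(config$subjects))
  for (i in seq_along(config$subjects)) {
    sub <- config$subjects[[i]]
    for (f in c("id", "sex", "group", "height", "weight", "age",
                "heart_rate"))
      if (is.null(sub[[f]])) stop_cmr("subject %d missing field '%s'", i, f)
    base <- if (identical(sub$group, "athlete")) "athlete" else "hcm"
    over <- if (is.null(sub$phantom)) list() else sub$phantom
    over$seed <- seed + i
    spec <- stage("phantom_spec", sub$id,
                  do.call(phantom_spec,
                          utils::modifyList(default_subject_phantoms[[base]],
                                            over)))
    ph <- stage("generate_phantom", sub$id, generate_phantom(spec))
    vcq <- stage("cq_quantify", sub$id,
                 cq_quantify(ph$stack, ph$contours, density))
    vtq <- stage("tq_quantify", sub$id,
                 tq_quantify(ph$stack, ph$contours, thr, density))
    wall <- stage("measure_edwt", sub$id, measure_edwt(ph$contours$ED))
    bsa <- stage("compute_bsa", sub$id, compute_bsa(sub$height, sub$weight))
    si <- stage("compute_sport_indices", sub$id,
                compute_sport_indices(wall, vcq, vtq, bsa))
    cls <- stage("classify_subject", sub$id, classify_subject(si, rules))
    row <- data.frame(subject_id = sub$id, group = sub$group, sex = sub$sex,
                      bsa = round(bsa, 6), stringsAsFactors = FALSE)
    for (nm in names(si)) row[[nm]] <- round(si[[nm]], 6)
    for (j in seq_len(nrow(cls$labels)))
      row[[paste0("label_", cls$labels$index[j])]] <- cls$labels$label[j]
    row$grey_zone <- cls$grey_zone
    rows[[i]] <- row
  }
  indices <- do.call(rbind, rows)
  utils::write.csv(indices, file.path(config$out_dir, "indices.csv"),
                   row.names = FALSE)

  diag_label <- ifelse(indices$group == "athlete", "athlete", "HCM")
  rocs <- list()
  if (length(unique(diag_label)) == 2L) {
    tab <- NULL
    for (idx in unique(rules$index)) {
      r <- optimal_cutoff(roc_curve(indices[[idx]], diag_label,
                                    positive = "HCM"))
      rocs[[idx]] <- r
      tab <- rbind(tab, data.frame(
        index = idx, cutoff = r$optimal_threshold, auc = round(r$auc, 3),
        sensitivity = round(r$at_optimum$sensitivity, 1),
        specificity = round(r$at_optimum$specificity, 1),
        ppv = round(r$at_optimum$ppv, 1), npv = round(r$at_optimum$npv, 1),
        correctly_classified = round(r$at_optimum$correctly_classified, 1),
        stringsAsFactors = FALSE))
    }
    jsonlite::write_json(
      lapply(rocs, function(r) list(
        auc = r$auc, optimal_threshold = r$optimal_threshold,
        confusion = as.list(r$confusion),
        at_optimum = r$at_optimum[c("sensitivity", "specificity", "ppv",
                                    "npv", "correctly_classified")])),
      file.path(config$out_dir, "roc.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(tab, file.path(config$out_dir, "cutoff_table.csv"),
                     row.names = FALSE)
  }
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                               auto_unbox = TRUE, force = TRUE, digits = NA)
  jsonlite::write_json(
    list(config_hash = config_hash(as.character(cfg_json)), seed = seed,
         package = "cmrsport",
         version = as.character(utils::packageVersion("cmrsport")),
         r_version = as.character(getRversion())),
    file.path(config$out_dir, "provenance.json"), auto_unbox = TRUE)
  invisible(list(indices = indices, rocs = rocs))
}
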