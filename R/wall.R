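# End-diastolic wall thickness (EDWT) along the myocardial centerline.
# The centerline is the closed mid-wall curve between the endocardial and
# epicardial contours; thickness at a centerline sample is the length of the
# compact-wall crossing of the chord through the sample perpendicular to the
# local centerline tangent. The maximum is taken over all slices; the
# minimum within the slice holding the maximum, as the max/min ratio is a
# within-slice asymmetry measure.

polygon_centroid <- function(poly) {
  p <- as_polygon(poly)
  j <- c(2:nrow(p), 1L)
  cr <- p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L]
  a <- sum(cr) / 2
  c(sum((p[, 1L] + p[j, 1L]) * cr), sum((p[, 2L] + p[j, 2L]) * cr)) / (6 * a)
}

#' Mid-wall myocardial centerline of one slice
#'
#' Samples rays from the cavity centroid; each centerline point is the
#' midpoint between the endocardial and epicardial boundary crossings along
#' a ray, and tangents come from central differences along the closed curve.
#'
#' @param endo,epi endocardial / epicardial polygons (n x 2 mm coordinates),
#'   endo strictly inside epi.
#' @param n_samples number of rays (>= 16).
#' @return List with `points` (n x 2), `tangents` (n x 2 unit vectors), and
#'   `centroid`.
#' @export
myocardial_centerline <- function(endo, epi, n_samples = 360L) {
  if (n_samples < 16L) stop_cmr("'n_samples' must be >= 16")
  endo <- as_polygon(endo, "endo"); epi <- as_polygon(epi, "epi")
  if (!all(points_in_polygon(endo[, 1L], endo[, 2L], epi)))
    stop_cmr("endocardial contour must lie strictly inside the epicardial contour")
  ctr <- polygon_centroid(endo)
  th <- 2 * pi * (seq_len(n_samples) - 1L) / n_samples
  pts <- matrix(NA_real_, n_samples, 2L)
  for (i in seq_len(n_samples)) {
    d <- c(cos(th[i]), sin(th[i]))
    te <- line_polygon_crossings(ctr, d, endo)
    tp <- line_polygon_crossings(ctr, d, epi)
    te <- te[te > 0]; tp <- tp[tp > 0]
    if (!length(te) || !length(tp))
      stop_cmr("ray from centroid failed to cross both contours")
    t_endo <- te[1L]; t_epi <- tp[tp > t_endo][1L]
    if (is.na(t_epi) || t_epi - t_endo < 1e-9)
      stop_cmr("degenerate wall: endocardial and epicardial contours coincide")
    pts[i, ] <- ctr + d * (t_endo + t_epi) / 2
  }
  nxt <- c(2:n_samples, 1L); prv <- c(n_samples, 1:(n_samples - 1L))
  tg <- pts[nxt, ] - pts[prv, ]
  tg <- tg / sqrt(rowSums(tg^2))
  list(points = pts, tangents = tg, centroid = ctr)
}

# thickness of the compact wall along the chord through point p
# perpendicular to tangent tg; NA when the chord misses a boundary
chord_thickness <- function(p, tg, endo, epi, centroid) {
  nrm <- c(-tg[2L], tg[1L])
  if (sum(nrm * (p - centroid)) < 0) nrm <- -nrm   # orient outward
  t_epi <- line_polygon_crossings(p, nrm, epi)
  t_epi <- t_epi[t_epi > 0]
  t_endo <- line_polygon_crossings(p, nrm, endo)
  t_endo <- t_endo[t_endo < 0]
  if (!length(t_epi) || !length(t_endo)) return(NA_real_)
  # clip to the first epicardial crossing outward, nearest endo crossing inward
  t_epi[1L] - t_endo[length(t_endo)]
}

#' Measure end-diastolic wall thickness
#'
#' Per slice, thickness is sampled at `n_chords` centerline points as the
#' perpendicular-chord length through the compact wall. Returns the maximum
#' over all slices, the minimum within the slice holding the maximum, their
#' ratio, and the full thickness profile. Chords that fail to cross both
#' boundaries are skipped; a skip fraction above 10% sets
#' `status = "warning"`.
#'
#' @param ed_contours list per slice with `endo` and `epi` polygons of the
#'   end-diastolic phase (e.g. `phantom$contours$ED`).
#' @param n_chords chords per slice (default 360, i.e. 1 degree spacing).
#' @return An `edwt_result`: `max_edwt`, `min_edwt`, `slice_of_max`,
#'   `max_min_ratio`, `profile` (slice x chord, mm), `skipped_fraction`,
#'   `status`.
#' @export
measure_edwt <- function(ed_contours, n_chords = 360L) {
  if (!length(ed_contours)) stop_cmr("no slices with contours")
  n_sl <- length(ed_contours)
  profile <- matrix(NA_real_, n_sl, n_chords)
  for (s in seq_len(n_sl)) {
    sl <- ed_contours[[s]]
    if (is.null(sl$endo) || is.null(sl$epi))
      stop_cmr("EDWT needs endo and epi contours on every slice (slice %d)", s)
    cl <- myocardial_centerline(sl$endo, sl$epi, n_chords)
    for (i in seq_len(n_chords))
      profile[s, i] <- chord_thickness(cl$points[i, ], cl$tangents[i, ],
                                       sl$endo, sl$epi, cl$centroid)
  }
  skipped <- mean(is.na(profile))
  if (all(is.na(profile))) stop_cmr("no valid thickness chords")
  max_edwt <- max(profile, na.rm = TRUE)
  slice_of_max <- which(profile == max_edwt, arr.ind = TRUE)[1L, 1L]
  min_edwt <- min(profile[slice_of_max, ], na.rm = TRUE)
  structure(list(max_edwt = max_edwt, min_edwt = min_edwt,
                 slice_of_max = as.integer(slice_of_max),
                 max_min_ratio = max_edwt / min_edwt,
                 profile = profile, skipped_fraction = skipped,
                 status = if (skipped > 0.1) "warning" else "ok"),
            class = "edwt_result")
}

#' @export
print.edwt_result <- function(x, ...) {
  cat(sprintf("EDWT: max %.1f mm (slice %d), min %.1f mm, max/min %.2f [%s]\n",
              x$max_edwt, x$slice_of_max, x$min_edwt, x$max_min_ratio,
              x$status))
  invisible(x)
}

#' @export
plot.edwt_result <- function(x, slice = x$slice_of_max, ...) {
  ang <- seq(0, 360, length.out = ncol(x$profile) + 1L)[-1L]
  graphics::plot(ang, x$profile[slice, ], type = "l", xlab = "angle (deg)",
                 ylab = "wall thickness (mm)",
                 main = sprintf("Wall thickness profile, slice %d", slice),
                 ...)
  graphics::abline(h = c(x$max_edwt, x$min_edwt), lty = 3)
  invisible(x)
}
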