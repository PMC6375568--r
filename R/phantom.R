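# Synthetic left-ventricular phantom: a stack of short-axis slices in which
# the LV is a thick-walled annulus with a bright blood pool, a darker compact
# wall whose thickness varies with angle (von Mises bump emulating asymmetric
# septal thickening), and dark intracavitary structures (papillary-muscle
# cylinders and trabecular ridges on the endocardial surface). Two cardiac
# phases are produced (end-diastole and end-systole). Ground truth comes from
# counting classes on a supersampled lattice, independent of any
# quantification code.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specify a synthetic left-ventricular phantom
#'
#' Parameters of the voxelized two-phase LV phantom. The compact wall has
#' angular thickness `t(theta) = wall_base + wall_bump_amplitude *
#' exp((cos(theta - wall_bump_center) - 1) / wall_bump_width^2)` (mm), so the
#' maximal wall thickness is `wall_base + wall_bump_amplitude` at the bump
#' center; `wall_bump_amplitude = 0` gives a symmetric, athlete-like ring.
#' Trabeculae occupy an angular fraction `trabecular_fraction` of a band of
#' depth `trabecular_depth` just inside the endocardial surface; papillary
#' muscles are `n_papillary` cylinders (first two at +/-60 degrees from the
#' bump center) present on the central 40% of slices.
#'
#' @param n_slices number of short-axis slices.
#' @param slice_thickness slice thickness, mm (default 8, no interslice gap).
#' @param slice_gap interslice gap, mm.
#' @param in_plane_spacing in-plane voxel spacing, mm.
#' @param grid_size voxels per in-plane axis; `NULL` auto-sizes to cover the
#'   epicardial extent with a 4 mm margin.
#' @param endo_radius_ed,endo_radius_es endocardial radius at end-diastole /
#'   end-systole, mm (`endo_radius_ed > endo_radius_es > 0`).
#' @param wall_base base compact wall thickness, mm.
#' @param wall_bump_amplitude extra thickness at the bump center, mm.
#' @param wall_bump_center bump center angle, radians.
#' @param wall_bump_width bump angular width parameter, radians.
#' @param n_papillary number of papillary-muscle cylinders.
#' @param papillary_radius papillary cylinder radius, mm.
#' @param trabecular_fraction angular fraction of the subendocardial band
#'   occupied by trabeculae, in [0, 0.3].
#' @param trabecular_depth radial depth of the trabecular band, mm.
#' @param blood_intensity,muscle_intensity signal intensities (arbitrary
#'   units, blood brighter than muscle); background is 0.
#' @param noise_sigma SD of additive Gaussian intensity noise.
#' @param supersampling_factor integer >= 1; each acquisition voxel is
#'   averaged from a `k x k` subgrid, creating partial-volume intensities.
#' @param seed integer seed controlling the noise draw.
#' @return A `phantom_spec` object (validated list).
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(n_slices = 10L, slice_thickness = 8, slice_gap = 0,
                         in_plane_spacing = 1, grid_size = NULL,
                         endo_radius_ed = 25, endo_radius_es = 18,
                         wall_base = 10, wall_bump_amplitude = 0,
                         wall_bump_center = 0, wall_bump_width = 0.6,
                         n_papillary = 0L, papillary_radius = 4,
                         trabecular_fraction = 0, trabecular_depth = 3,
                         blood_intensity = 1000, muscle_intensity = 200,
                         noise_sigma = 0, supersampling_factor = 4L,
                         seed = 1L) {
  check_positive(n_slices, "n_slices")
  check_positive(slice_thickness, "slice_thickness")
  check_positive(in_plane_spacing, "in_plane_spacing")
  check_positive(wall_base, "wall_base")
  check_positive(wall_bump_width, "wall_bump_width")
  if (slice_gap < 0) stop_cmr("'slice_gap' must be >= 0")
  if (!(endo_radius_ed > endo_radius_es && endo_radius_es > 0))
    stop_cmr("need endo_radius_ed > endo_radius_es > 0")
  if (wall_bump_amplitude < 0) stop_cmr("'wall_bump_amplitude' must be >= 0")
  if (trabecular_fraction < 0 || trabecular_fraction > 0.3)
    stop_cmr("'trabecular_fraction' must be in [0, 0.3]")
  if (trabecular_fraction > 0 && trabecular_depth >= endo_radius_es)
    stop_cmr("'trabecular_depth' must be smaller than endo_radius_es")
  if (blood_intensity <= muscle_intensity)
    stop_cmr("'blood_intensity' must exceed 'muscle_intensity'")
  if (noise_sigma < 0) stop_cmr("'noise_sigma' must be >= 0")
  if (supersampling_factor < 1 || supersampling_factor != round(supersampling_factor))
    stop_cmr("'supersampling_factor' must be an integer >= 1")
  max_epi <- endo_radius_ed + wall_base + wall_bump_amplitude
  if (is.null(grid_size)) {
    grid_size <- ceiling(2 * (max_epi + 4) / in_plane_spacing)
    grid_size <- grid_size + grid_size %% 2L
  }
  if (grid_size * in_plane_spacing < 2 * max_epi)
    stop_cmr(paste("grid too small: %d voxels at %.3g mm cover %.1f mm but",
                   "the epicardium extends over %.1f mm"),
             grid_size, in_plane_spacing, grid_size * in_plane_spacing,
             2 * max_epi)
  spec <- list(n_slices = as.integer(n_slices),
               slice_thickness = slice_thickness, slice_gap = slice_gap,
               in_plane_spacing = in_plane_spacing,
               grid_size = as.integer(grid_size),
               endo_radius_ed = endo_radius_ed,
               endo_radius_es = endo_radius_es,
               wall_base = wall_base,
               wall_bump_amplitude = wall_bump_amplitude,
               wall_bump_center = wall_bump_center,
               wall_bump_width = wall_bump_width,
               n_papillary = as.integer(n_papillary),
               papillary_radius = papillary_radius,
               trabecular_fraction = trabecular_fraction,
               trabecular_depth = trabecular_depth,
               blood_intensity = blood_intensity,
               muscle_intensity = muscle_intensity,
               noise_sigma = noise_sigma,
               supersampling_factor = as.integer(supersampling_factor),
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

# angular wall thickness, mm
wall_thickness_fun <- function(spec, theta) {
  spec$wall_base + spec$wall_bump_amplitude *
    exp((cos(theta - spec$wall_bump_center) - 1) / spec$wall_bump_width^2)
}

papillary_angles <- function(spec) {
  n <- spec$n_papillary
  if (n == 0L) return(numeric(0))
  ang <- spec$wall_bump_center + c(-1, 1) * pi / 3
  if (n == 1L) return(ang[1L])
  if (n > 2L)
    ang <- c(ang, spec$wall_bump_center + pi +
               2 * pi * (seq_len(n - 2L) - 1L) / (n - 2L))
  ang[seq_len(n)]
}

# which slices carry papillary muscles: central 40% run
papillary_slices <- function(spec) {
  if (spec$n_papillary == 0L) return(integer(0))
  k <- max(1L, round(0.4 * spec$n_slices))
  start <- floor((spec$n_slices - k) / 2) + 1L
  seq.int(start, start + k - 1L)
}

# Classify the supersampled lattice of one slice type.
# Returns an integer matrix (0 background, 1 blood, 2 compact muscle, 3 TPM)
# of size (grid*k) x (grid*k).
classify_subgrid <- function(spec, endo_radius, with_papillary) {
  k <- spec$supersampling_factor
  g <- spec$grid_size
  step <- spec$in_plane_spacing / k
  pos <- (seq_len(g * k) - 0.5) * step - g * spec$in_plane_spacing / 2
  x <- matrix(pos, g * k, g * k)
  y <- matrix(pos, g * k, g * k, byrow = TRUE)
  r <- sqrt(x^2 + y^2)
  th <- atan2(y, x)
  epi_r <- endo_radius + wall_thickness_fun(spec, th)
  cls <- matrix(0L, g * k, g * k)
  cls[r <= epi_r] <- 2L             # compact wall (overwritten inside endo)
  inside <- r <= endo_radius
  cls[inside] <- 1L                 # blood
  if (spec$trabecular_fraction > 0) {
    n_ridges <- 16L
    phase <- ((th - spec$wall_bump_center) %% (2 * pi / n_ridges)) /
      (2 * pi / n_ridges)
    trab <- inside & r > endo_radius - spec$trabecular_depth &
      phase < spec$trabecular_fraction
    cls[trab] <- 3L
  }
  if (with_papillary && spec$n_papillary > 0L) {
    for (a in papillary_angles(spec)) {
      cx <- 0.55 * endo_radius * cos(a)
      cy <- 0.55 * endo_radius * sin(a)
      pap <- inside & (x - cx)^2 + (y - cy)^2 <= spec$papillary_radius^2
      cls[pap] <- 3L
    }
  }
  cls
}

# average a (g*k) x (g*k) matrix down to g x g blocks
block_mean <- function(m, k) {
  if (k == 1L) return(m)
  g <- nrow(m) / k
  m <- matrix(colMeans(matrix(m, nrow = k)), nrow = g)      # rows
  t(matrix(colMeans(matrix(t(m), nrow = k)), nrow = g))     # cols
}

circle_polygon <- function(radius_fun, center, n = 256L) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  r <- radius_fun(th)
  cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
}

#' Generate a two-phase LV phantom with contours and ground truth
#'
#' Voxelizes the phantom described by a [phantom_spec()] at supersampled
#' resolution, averages down to the acquisition grid (partial volume), adds
#' Gaussian noise, and returns the image stack, the endocardial/epicardial
#' contour polygons (the endocardial contour is the smooth cavity boundary,
#' so trabeculae and papillary muscles lie inside it), and analytic ground
#' truth (cavity, compact-wall and TPM volumes from supersampled voxel
#' counting; wall-thickness field from the analytic thickness function).
#'
#' @param spec a `phantom_spec`.
#' @return An object of class `lv_phantom`: list with `stack`
#'   (a `sax_stack`), `contours` (a `contour_set`), `truth`
#'   (a `phantom_truth`), and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(n_slices = 4, in_plane_spacing = 2,
#'                                     supersampling_factor = 2))
#' ph$truth$cavity_volume_ed
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  g <- spec$grid_size
  k <- spec$supersampling_factor
  pap_sl <- papillary_slices(spec)
  center <- rep(g * spec$in_plane_spacing / 2, 2L)
  slab <- spec$slice_thickness + spec$slice_gap
  subvol <- (spec$in_plane_spacing / k)^2 * slab     # mm^3 per subvoxel

  intens <- c(0, spec$blood_intensity, spec$muscle_intensity,
              spec$muscle_intensity)                 # class 0..3

  phases <- list(ED = spec$endo_radius_ed, ES = spec$endo_radius_es)
  stack_phases <- list()
  counts <- list()
  for (ph in names(phases)) {
    cls_plain <- classify_subgrid(spec, phases[[ph]], with_papillary = FALSE)
    cls_pap <- if (length(pap_sl))
      classify_subgrid(spec, phases[[ph]], with_papillary = TRUE) else NULL
    img_plain <- block_mean(matrix(intens[cls_plain + 1L], nrow(cls_plain)), k)
    img_pap <- if (!is.null(cls_pap))
      block_mean(matrix(intens[cls_pap + 1L], nrow(cls_pap)), k) else NULL
    vol <- array(0, dim = c(g, g, spec$n_slices))
    cnt <- c(blood = 0, compact = 0, tpm = 0)
    tab_plain <- tabulate(cls_plain + 1L, nbins = 4L)
    tab_pap <- if (!is.null(cls_pap)) tabulate(cls_pap + 1L, nbins = 4L)
    for (s in seq_len(spec$n_slices)) {
      pap_here <- s %in% pap_sl
      vol[, , s] <- if (pap_here) img_pap else img_plain
      tb <- if (pap_here) tab_pap else tab_plain
      cnt <- cnt + tb[2:4]
    }
    counts[[ph]] <- cnt * subvol
    stack_phases[[ph]] <- vol
  }

  if (spec$noise_sigma > 0) {
    stack_phases <- with_seed(spec$seed, lapply(stack_phases, function(v)
      v + array(stats::rnorm(length(v), sd = spec$noise_sigma), dim = dim(v))))
  }

  stack <- structure(list(phases = stack_phases,
                          in_plane_spacing = spec$in_plane_spacing,
                          slice_thickness = spec$slice_thickness,
                          slice_gap = spec$slice_gap),
                     class = "sax_stack")

  contours <- list()
  for (ph in names(phases)) {
    r_endo <- phases[[ph]]
    endo <- circle_polygon(function(t) rep(r_endo, length(t)), center)
    epi <- circle_polygon(function(t) r_endo + wall_thickness_fun(spec, t),
                          center)
    contours[[ph]] <- lapply(seq_len(spec$n_slices),
                             function(s) list(endo = endo, epi = epi))
  }
  contours <- structure(contours, class = "contour_set")

  th_fine <- seq(0, 2 * pi, length.out = 3601L)[-3601L]
  t_fine <- wall_thickness_fun(spec, th_fine)
  profile <- matrix(rep(t_fine, each = spec$n_slices), nrow = spec$n_slices)
  truth <- structure(list(
    cavity_volume_ed = mm3_to_ml(counts$ED[["blood"]]),
    cavity_volume_es = mm3_to_ml(counts$ES[["blood"]]),
    compact_myo_volume = mm3_to_ml(counts$ED[["compact"]]),
    tpm_volume = mm3_to_ml(counts$ED[["tpm"]]),
    tpm_volume_es = mm3_to_ml(counts$ES[["tpm"]]),
    max_wall_thickness = max(t_fine),
    min_wall_thickness_same_slice = min(t_fine),
    thickness_profile = profile,
    profile_angles = th_fine), class = "phantom_truth")

  structure(list(stack = stack, contours = contours, truth = truth,
                 spec = spec), class = "lv_phantom")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "LV phantom spec: %d slices x %g mm, %g mm in-plane (%d voxels)\n",
    x$n_slices, x$slice_thickness, x$in_plane_spacing, x$grid_size))
  cat(sprintf("  endo radius ED/ES %g/%g mm; wall %g mm + bump %g mm\n",
              x$endo_radius_ed, x$endo_radius_es, x$wall_base,
              x$wall_bump_amplitude))
  cat(sprintf("  TPM: %d papillary (r=%g mm), trabecular fraction %.2f\n",
              x$n_papillary, x$papillary_radius, x$trabecular_fraction))
  invisible(x)
}

#' @export
print.lv_phantom <- function(x, ...) {
  print(x$spec)
  tr <- x$truth
  cat(sprintf(
    "  truth: cavity ED %.1f ml, ES %.1f ml, compact %.1f ml, TPM %.1f ml\n",
    tr$cavity_volume_ed, tr$cavity_volume_es, tr$compact_myo_volume,
    tr$tpm_volume))
  cat(sprintf("  wall thickness %.1f-%.1f mm\n",
              tr$min_wall_thickness_same_slice, tr$max_wall_thickness))
  invisible(x)
}
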