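# Small phantoms and geometric helpers reused across tests.

# coarse, fast annular phantom (uniform wall, no TPM unless overridden)
quick_spec <- function(...) {
  args <- utils::modifyList(
    list(n_slices = 4L, in_plane_spacing = 2, supersampling_factor = 2,
         endo_radius_ed = 25, endo_radius_es = 18, wall_base = 10),
    list(...))
  do.call(phantom_spec, args)
}

circle_poly <- function(r, center = c(0, 0), n = 128L) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
}

# minimal stack carrying only geometry (for contour-only operations)
geometry_stack <- function(slice_thickness = 8, slice_gap = 0,
                           in_plane_spacing = 1) {
  structure(list(phases = list(), in_plane_spacing = in_plane_spacing,
                 slice_thickness = slice_thickness, slice_gap = slice_gap),
            class = "sax_stack")
}

# independent all-pairs Mann-Whitney concordance (half-credit ties)
concordance_oracle <- function(values, pos) {
  x <- values[pos]; y <- values[!pos]
  s <- 0
  for (xi in x) for (yj in y) s <- s + (xi > yj) + 0.5 * (xi == yj)
  s / (length(x) * length(y))
}

# exhaustive accuracy search over every candidate threshold
best_accuracy_oracle <- function(values, pos) {
  ux <- sort(unique(values))
  thr <- c(-Inf, if (length(ux) > 1) (ux[-1] + ux[-length(ux)]) / 2, Inf)
  max(vapply(thr, function(t)
    (sum(pos & values > t) + sum(!pos & values <= t)) / length(values),
    numeric(1)))
}
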