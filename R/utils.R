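#' @keywords internal
"_PACKAGE"

# Shared geometry and validation helpers. Polygons are n x 2 matrices of
# planar mm coordinates; closure is implicit (last vertex joins the first).

stop_cmr <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop_cmr("'%s' must be a positive finite number", name)
  invisible(x)
}

as_polygon <- function(p, name = "polygon") {
  p <- as.matrix(p)
  if (ncol(p) != 2L || nrow(p) < 3L || any(!is.finite(p)))
    stop_cmr("'%s' must be a finite n x 2 matrix with n >= 3", name)
  # drop an explicitly repeated closing vertex
  if (isTRUE(all.equal(p[1L, ], p[nrow(p), ], check.attributes = FALSE)))
    p <- p[-nrow(p), , drop = FALSE]
  unname(p)
}

#' Signed and absolute polygon area (shoelace formula)
#'
#' Area of a simple closed polygon given its vertices in order, by the
#' shoelace formula on the planar coordinates. Units are the square of the
#' coordinate units (mm^2 for contour polygons).
#'
#' @param poly numeric matrix, n x 2, vertices in order (closure implicit).
#' @return Absolute enclosed area (non-negative scalar).
#' @examples
#' polygon_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))  # unit square -> 1
#' @export
polygon_area <- function(poly) {
  p <- as_polygon(poly)
  x <- p[, 1L]; y <- p[, 2L]
  j <- c(2:nrow(p), 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Test points for polygon membership
#'
#' Even-odd (ray crossing) membership of points in a simple closed polygon,
#' vectorized over points. Points exactly on an edge follow the crossing
#' rule's side assignment; voxel-center tests on contour data are insensitive
#' to this at any realistic resolution.
#'
#' @param px,py numeric vectors of point coordinates (equal length).
#' @param poly polygon as an n x 2 matrix.
#' @return Logical vector, `TRUE` where the point lies inside.
#' @export
points_in_polygon <- function(px, py, poly) {
  p <- as_polygon(poly)
  n <- nrow(p)
  inside <- logical(length(px))
  xj <- p[n, 1L]; yj <- p[n, 2L]
  for (i in seq_len(n)) {
    xi <- p[i, 1L]; yi <- p[i, 2L]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py[crosses] - yi) * (xj - xi) / (yj - yi)
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
    xj <- xi; yj <- yi
  }
  inside
}

# Intersections of the directed line c + t * d with a polygon boundary.
# Returns sorted parameter values t of all boundary crossings.
line_polygon_crossings <- function(center, direction, poly) {
  p <- as_polygon(poly)
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1L), , drop = FALSE]
  ex <- b[, 1L] - a[, 1L]; ey <- b[, 2L] - a[, 2L]
  dx <- direction[1L];      dy <- direction[2L]
  den <- dx * ey - dy * ex
  ok <- abs(den) > 1e-12
  wx <- a[, 1L] - center[1L]; wy <- a[, 2L] - center[2L]
  t <- (wx * ey - wy * ex) / den    # along the ray
  s <- (wx * dy - wy * dx) / den    # along the edge
  # half-open tolerance window so a crossing exactly at a vertex is counted
  # on exactly one of the two adjacent edges
  hit <- ok & s >= -1e-9 & s < 1 - 1e-9
  sort(t[hit])
}

# Two-class split of an intensity sample: Otsu's criterion (maximal
# between-class variance) over candidate cuts at midpoints of adjacent
# distinct values. Returns the two class means (low, high) and the cut.
otsu_split <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || diff(range(x)) <= .Machine$double.eps * max(abs(x), 1))
    return(list(degenerate = TRUE, low = NA_real_, high = NA_real_,
                cut = NA_real_))
  xs <- sort(x)
  ux <- unique(xs)
  if (length(ux) == 2L) {
    lo <- ux[1L]; hi <- ux[2L]
    return(list(degenerate = FALSE, low = lo, high = hi,
                cut = (lo + hi) / 2))
  }
  cuts <- (ux[-1L] + ux[-length(ux)]) / 2
  n <- length(xs)
  csum <- cumsum(xs)
  # for each cut, index of last value <= cut
  k <- findInterval(cuts, xs)
  w0 <- k / n
  mu0 <- csum[k] / k
  mu1 <- (csum[n] - csum[k]) / (n - k)
  between <- w0 * (1 - w0) * (mu0 - mu1)^2
  best <- which.max(between)
  kb <- k[best]
  list(degenerate = FALSE, low = csum[kb] / kb,
       high = (csum[n] - csum[kb]) / (n - kb), cut = cuts[best])
}

# mm^3 -> ml
mm3_to_ml <- function(v) v / 1000
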