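# Internal geometry and numeric helpers shared across modules.
# All physical coordinates are mm in the image frame: x along columns
# (anterior-positive unless stated otherwise), y along rows (distal-ward for
# the tibia, i.e. increasing downwards).

`%||%` <- function(a, b) if (is.null(a)) b else a

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

# 90-degree counter-clockwise rotation in (x, y) with y pointing down this is
# visually clockwise; used only to build normals, orientation fixed afterwards
perp_vec <- function(v) c(-v[2], v[1])

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Signed perpendicular distance of points (n x 2) from the line through
# `point` with direction `dir`, measured along `normal` (unit).
signed_dist_line <- function(pts, point, dir, normal) {
  pts <- matrix(pts, ncol = 2)
  (pts[, 1] - point[1]) * normal[1] + (pts[, 2] - point[2]) * normal[2]
}

# Normal to `dir` oriented so that it has positive dot product with `toward`.
oriented_normal <- function(dir, toward) {
  n <- unit_vec(perp_vec(dir))
  if (sum(n * toward) < 0) n <- -n
  n
}

# Intersection of the infinite line (p, d) with segment a--b, or NULL.
line_segment_intersection <- function(p, d, a, b) {
  n <- perp_vec(d)
  fa <- sum((a - p) * n)
  fb <- sum((b - p) * n)
  if ((fa > 0 && fb > 0) || (fa < 0 && fb < 0)) return(NULL)
  if (fa == fb) return(NULL)           # segment parallel to (or on) the line
  t <- fa / (fa - fb)
  a + t * (b - a)
}

# All intersections of line (p, d) with a closed polyline (k x 2 matrix).
line_polygon_intersections <- function(p, d, poly) {
  k <- nrow(poly)
  out <- list()
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    hit <- line_segment_intersection(p, d, poly[i, ], poly[j, ])
    if (!is.null(hit)) out[[length(out) + 1L]] <- hit
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, out)
}

# Shoelace area of a closed polygon (k x 2), positive regardless of winding.
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

# Bilinear interpolation of matrix `m` at fractional (row, col) positions.
# Positions outside the matrix are clamped to the border.
bilinear_sample <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  row <- pmin(pmax(row, 1), nr)
  col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(row), nr - 1L); c0 <- pmin(floor(col), nc - 1L)
  fr <- row - r0; fc <- col - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Sub-pixel peak location by parabolic interpolation through three samples
# (y_left, y_centre, y_right) of a maximum; returns offset in (-0.5, 0.5).
parabolic_peak_offset <- function(yl, yc, yr) {
  den <- yl - 2 * yc + yr
  off <- ifelse(abs(den) < .Machine$double.eps, 0, 0.5 * (yl - yr) / den)
  pmin(pmax(off, -0.5), 0.5)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}
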