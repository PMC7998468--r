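#' Axis line constructor
#'
#' A shaft axis as an (origin point, unit direction) pair in mm. The
#' direction always points *away* from the joint space, so angles between
#' axes have an unambiguous meaning.
#'
#' @param point length-2 mm coordinate on the line.
#' @param direction length-2 direction; normalized internally.
#' @param role `"femoral"` or `"tibial"`.
#' @return An object of class `axis_line`.
#' @export
axis_line <- function(point, direction, role = c("femoral", "tibial")) {
  role <- match.arg(role)
  structure(list(point = as.numeric(point), direction = unit_vec(direction),
                 role = role), class = "axis_line")
}

#' @export
print.axis_line <- function(x, ...) {
  cat(sprintf("<axis_line %s> through (%.2f, %.2f) mm, direction (%.4f, %.4f)\n",
              x$role, x$point[1], x$point[2], x$direction[1], x$direction[2]))
  invisible(x)
}

#' Locate the knee joint row from the row-sum profile
#'
#' The joint space holds the least bone of any row near the image centre, so
#' the sum of gray values over each row dips there. Returns the row with the
#' deepest dip (global minimum of the row-sum profile) within a search band;
#' when several dips exist the deepest corresponds to the largest bone-free
#' gap.
#'
#' @param img an [image2d] (usually after [preprocess()]).
#' @param search_band integer length-2 row range; default the middle 60% of
#'   rows.
#' @return Integer row index (working resolution).
#' @export
locate_joint_row <- function(img, search_band = NULL) {
  stopifnot(inherits(img, "image2d"))
  nr <- nrow(img$pixels)
  if (is.null(search_band))
    search_band <- c(ceiling(0.2 * nr), floor(0.8 * nr))
  search_band <- as.integer(search_band)
  if (search_band[1] < 1L || search_band[2] > nr ||
      diff(search_band) < 2L)
    stop("'search_band' must lie within the image and span >= 3 rows")
  rows <- search_band[1]:search_band[2]
  rs <- rowSums(img$pixels[rows, , drop = FALSE])
  i <- which.min(rs)
  d <- diff(rs)
  if ((i == 1L || i == length(rs)) && (all(d > 0) || all(d < 0)))
    stop("no joint found: row-sum profile is strictly monotone over the band")
  rows[i]
}

# ---------------------------------------------------------------------------
# Minimal-cost monotone edge path (dynamic programming)

#' Minimal-cost monotone path through a cost grid
#'
#' Finds, by dynamic programming, the column sequence (one column per row,
#' rows strictly monotone) minimizing `sum(cost[row, col[row]]) +
#' beta * sum(|col[r+1] - col[r]|)` subject to `|col[r+1] - col[r]| <=
#' max_step`. This is the path model used for bone-edge segmentation, where
#' the intensity cost is low on strong oriented gradients and the shape term
#' keeps the path smooth.
#'
#' @param cost numeric matrix (rows x columns); `Inf` forbids a cell.
#' @param max_step maximum column change between consecutive rows.
#' @param beta per-pixel penalty on the column change.
#' @return list with `cols` (integer per row) and `total_cost`.
#' @export
edge_path_dp <- function(cost, max_step = 3L, beta = 0.25) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr < 1L || nc < 1L) stop("empty cost grid")
  D <- cost[1, ]
  back <- matrix(NA_integer_, nr, nc)
  steps <- seq.int(-max_step, max_step)
  for (r in seq_len(nr)[-1]) {
    best <- rep(Inf, nc); arg <- rep(NA_integer_, nc)
    for (dc in steps) {
      src <- seq_len(nc) - dc
      ok <- src >= 1L & src <= nc
      cand <- rep(Inf, nc)
      cand[ok] <- D[src[ok]] + beta * abs(dc)
      upd <- cand < best
      best[upd] <- cand[upd]
      arg[upd] <- src[upd]
    }
    D <- best + cost[r, ]
    back[r, ] <- arg
  }
  if (!any(is.finite(D))) stop("no path with finite cost")
  cols <- integer(nr)
  cols[nr] <- which.min(D)
  for (r in rev(seq_len(nr)[-1])) cols[r - 1L] <- back[r, cols[r]]
  list(cols = cols, total_cost = min(D))
}

# Track the bone cross-section (bright run) row by row, choosing in each row
# the run with the largest overlap with the previous row's run. Returns
# per-row [start, end] columns, NA where lost.
track_bone_run <- function(mask, init_row = 1L) {
  nr <- nrow(mask)
  runs_of <- function(v) {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(start = starts[r$values], end = ends[r$values])
  }
  out <- matrix(NA_integer_, nr, 2)
  order_rows <- c(seq(init_row, 1L), if (init_row < nr) seq(init_row + 1L, nr))
  prev <- NULL
  for (pass in list(seq(init_row, nr), if (init_row > 1L) seq(init_row - 1L, 1L))) {
    if (is.null(pass)) next
    prev <- if (!is.na(out[init_row, 1])) out[init_row, ] else NULL
    for (r in pass) {
      rr <- runs_of(mask[r, ])
      if (!nrow(rr)) next
      if (is.null(prev)) {
        pick <- which.max(rr[, 2] - rr[, 1])      # widest run to seed
      } else {
        ov <- pmin(rr[, 2], prev[2]) - pmax(rr[, 1], prev[1])
        if (max(ov) < 0) next                     # lost track this row
        pick <- which.max(ov)
      }
      out[r, ] <- rr[pick, ]
      prev <- out[r, ]
    }
  }
  out
}

#' Segment the anterior and posterior edges of a bone shaft
#'
#' Tracks the bright bone cross-section row by row on the bone's side of the
#' joint, then finds each edge as the minimal-cost monotone path where the
#' cost rewards a strong gray-value gradient of the correct sign across the
#' path (bone is brighter than soft tissue, so the posterior edge is a
#' rising and the anterior edge a falling gradient along the anterior
#' direction) and penalizes column jumps. Edge columns are refined to
#' sub-pixel precision by parabolic interpolation of the gradient magnitude.
#'
#' @param img working-resolution [image2d].
#' @param joint_row joint row index from [locate_joint_row()].
#' @param bone `"femur"` or `"tibia"`.
#' @param params segmentation parameters, see [run_config()]; uses `alpha`,
#'   `beta`, `max_step`, `corridor_px`.
#' @return list with `anterior` and `posterior` edge paths, each a
#'   data.frame `(row, col)` (col fractional) with attribute `role`.
#' @export
segment_bone_edges <- function(img, joint_row, bone = c("femur", "tibia"),
                               params = run_config()) {
  bone <- match.arg(bone)
  px <- img$pixels
  s <- img$spacing_mm
  nr <- nrow(px); nc <- ncol(px)
  lo <- stats::quantile(px, 0.2); hi <- stats::quantile(px, 0.98)
  if (hi - lo < 1e-8)
    stop(sprintf("segmentation failure (%s): image has no contrast", bone))
  thr <- (lo + hi) / 2

  far <- round(145 / s)
  if (bone == "femur") {
    rows <- max(1L, joint_row - far):max(1L, joint_row - round(50 / s))
    init <- 1L                                    # seed farthest from joint
  } else {
    r0 <- joint_row
    while (r0 <= nr && max(px[r0, ]) < thr) r0 <- r0 + 1L
    if (r0 > nr)
      stop(sprintf("segmentation failure (%s): no bone below the joint", bone))
    rows <- min(nr, r0 + round(2 / s)):min(nr, joint_row + far)
    init <- length(rows)                          # seed farthest from joint
  }
  mask <- px[rows, , drop = FALSE] > thr
  run <- track_bone_run(mask, init_row = init)
  ok <- !is.na(run[, 1])
  if (sum(ok) < 5L)
    stop(sprintf("segmentation failure (%s): bone cross-section not found", bone))
  rows <- rows[ok]; run <- run[ok, , drop = FALSE]

  grad <- matrix(0, length(rows), nc)             # d/dcol, central difference
  sub <- px[rows, , drop = FALSE]
  grad[, 2:(nc - 1)] <- (sub[, 3:nc] - sub[, 1:(nc - 2)]) / 2

  ant_pos <- anterior_vec(img)[1] > 0             # TRUE: anterior = +col
  w <- params$corridor_px
  one_edge <- function(side) {                    # side: "low" or "high" col
    centre <- if (side == "low") run[, 1] else run[, 2]
    centre <- round(stats::runmed(centre, 1 + 2 * min(5, (length(centre) - 1) %/% 2)))
    sign_wanted <- if (side == "low") +1 else -1  # rising into bone at low col
    strength <- sign_wanted * grad
    smax <- max(strength)
    if (smax <= 0)
      stop(sprintf("segmentation failure (%s): no %s edge gradient", bone, side))
    cost <- params$alpha * (1 - strength / smax)
    corridor <- abs(col(cost) - centre[row(cost)]) > w
    cost[corridor] <- Inf
    res <- edge_path_dp(cost, max_step = params$max_step, beta = params$beta)
    cols <- res$cols
    # sub-pixel: parabolic peak of the signed gradient around the DP column
    cl <- pmax(cols - 1L, 1L); cr <- pmin(cols + 1L, nc)
    i <- seq_along(rows)
    off <- parabolic_peak_offset(strength[cbind(i, cl)],
                                 strength[cbind(i, cols)],
                                 strength[cbind(i, cr)])
    data.frame(row = rows, col = cols + off)
  }
  post <- one_edge(if (ant_pos) "low" else "high")
  ant <- one_edge(if (ant_pos) "high" else "low")
  attr(ant, "role") <- paste0(bone, "-anterior")
  attr(post, "role") <- paste0(bone, "-posterior")
  list(anterior = ant, posterior = post)
}

#' Fit a shaft axis as the total-least-squares midline of two edges
#'
#' Per-row midpoints of the anterior and posterior edge paths are taken over
#' the band of rows whose distance from the joint row lies in `band_mm`
#' (default 8--14 cm), and the axis is the total-least-squares line through
#' them (principal axis of the midpoint scatter), oriented away from the
#' joint.
#'
#' @param anterior,posterior edge paths from [segment_bone_edges()].
#' @param joint_row joint row index (working resolution).
#' @param spacing_mm working pixel spacing.
#' @param band_mm numeric length-2 distance band in mm.
#' @param origin_mm mm coordinate of pixel (1, 1) (from the [image2d]).
#' @return An [axis_line()] with role inferred from which side of the joint
#'   the edges lie.
#' @export
fit_axis <- function(anterior, posterior, joint_row, spacing_mm,
                     band_mm = c(80, 140), origin_mm = c(0, 0)) {
  rows <- intersect(anterior$row, posterior$row)
  dist_mm <- abs(rows - joint_row) * spacing_mm
  need <- rows[dist_mm >= band_mm[1] & dist_mm <= band_mm[2]]
  span <- range(dist_mm)
  # the band must be fully covered (up to one row of discretization slack)
  if (!length(need) || min(dist_mm) > band_mm[1] + spacing_mm ||
      max(dist_mm) < band_mm[2] - spacing_mm)
    stop(sprintf(
      "axis fit failed: edges cover %.0f-%.0f mm from the joint, need %.0f-%.0f mm",
      span[1], span[2], band_mm[1], band_mm[2]))
  ca <- anterior$col[match(need, anterior$row)]
  cp <- posterior$col[match(need, posterior$row)]
  mid <- cbind(x = origin_mm[1] + ((ca + cp) / 2 - 1) * spacing_mm,
               y = origin_mm[2] + (need - 1) * spacing_mm)
  ctr <- colMeans(mid)
  cc <- sweep(mid, 2, ctr)
  ev <- eigen(crossprod(cc), symmetric = TRUE)
  dir <- ev$vectors[, 1]                      # largest-eigenvalue direction
  femoral <- stats::median(need) < joint_row
  away_y <- if (femoral) -1 else 1            # away from joint along rows
  if (dir[2] * away_y < 0) dir <- -dir
  axis_line(ctr, dir, role = if (femoral) "femoral" else "tibial")
}

#' Rectangular region of interest around the femoral condyles
#'
#' Centred on the femoral-axis point at the joint row, axis-aligned to the
#' image, with the requested physical side length, clipped to the image.
#'
#' @param joint_row joint row index (working resolution).
#' @param femoral_axis an [axis_line()].
#' @param img working-resolution [image2d] (for spacing, origin and extent).
#' @param roi_size_mm side length in mm (scalar or length-2 `(rows, cols)`).
#' @return list with `rows`, `cols` (inclusive index ranges) and `center_px`.
#' @export
define_condyle_roi <- function(joint_row, femoral_axis, img,
                               roi_size_mm = 100) {
  stopifnot(inherits(femoral_axis, "axis_line"))
  size <- rep(roi_size_mm, length.out = 2L)
  s <- img$spacing_mm
  y_mm <- img$origin_mm[2] + (joint_row - 1) * s
  d <- femoral_axis$direction
  if (abs(d[2]) < 1e-9) stop("femoral axis parallel to the joint row")
  t <- (y_mm - femoral_axis$point[2]) / d[2]
  x_mm <- femoral_axis$point[1] + t * d[1]
  ctr <- mm_to_px(img, x_mm, y_mm)
  half <- size / 2 / s
  rows <- c(floor(ctr[1] - half[1]), ceiling(ctr[1] + half[1]))
  cols <- c(floor(ctr[2] - half[2]), ceiling(ctr[2] + half[2]))
  rows_c <- pmin(pmax(rows, 1L), nrow(img$pixels))
  cols_c <- pmin(pmax(cols, 1L), ncol(img$pixels))
  if (rows_c[1] >= rows_c[2] || cols_c[1] >= cols_c[2] ||
      rows[2] < 1L || rows[1] > nrow(img$pixels) ||
      cols[2] < 1L || cols[1] > ncol(img$pixels))
    stop("condyle ROI falls outside the image")
  list(rows = as.integer(rows_c), cols = as.integer(cols_c),
       center_px = c(row = ctr[1], col = ctr[2]))
}

#' Automated per-method quality control of a knee segmentation
#'
#' Stands in for the human landmark review of the original workflow with
#' heuristics: methods 1--3 require both shaft axes plus plausible condyle
#' margins (flexion angle within `[0, 90]` degrees, axes intersecting within
#' the image extended by 50%, each contour area within `[0.25, 4]` times the
#' shape model's mean area); method 4 additionally requires that the condyle
#' model fit converged for both condyles.
#'
#' @param seg a `knee_seg` from [segment_knee()].
#' @param model_mean_area_mm2 mean condyle area of the shape model; taken
#'   from `seg` when available.
#' @return Named logical vector `c(m1, m2, m3, m4)`.
#' @export
qc_segmentation <- function(seg, model_mean_area_mm2 = NULL) {
  model_mean_area_mm2 <- model_mean_area_mm2 %||% seg$model_mean_area_mm2
  axes_ok <- !is.null(seg$femoral_axis) && !is.null(seg$tibial_axis)
  base <- axes_ok
  if (axes_ok) {
    fl <- try(flexion_angle(seg), silent = TRUE)
    base <- base && !inherits(fl, "try-error") && fl >= 0 && fl <= 90
    # axes must intersect within the image grown by 50% on each side
    ext <- seg$extent_mm                      # c(xmin, xmax, ymin, ymax)
    if (!is.null(ext) && base) {
      u <- seg$femoral_axis$direction; v <- seg$tibial_axis$direction
      den <- u[1] * v[2] - u[2] * v[1]
      if (abs(den) < 1e-9) {
        base <- FALSE
      } else {
        dp <- seg$tibial_axis$point - seg$femoral_axis$point
        t1 <- (dp[1] * v[2] - dp[2] * v[1]) / den
        p <- seg$femoral_axis$point + t1 * u
        gx <- diff(ext[1:2]) / 2; gy <- diff(ext[3:4]) / 2
        base <- base &&
          p[1] >= ext[1] - gx && p[1] <= ext[2] + gx &&
          p[2] >= ext[3] - gy && p[2] <= ext[4] + gy
      }
    }
  }
  contours_ok <- !is.null(seg$condyle_contours) &&
    all(vapply(seg$condyle_contours, function(ct) {
      if (is.null(ct) || nrow(ct) < 3L) return(FALSE)
      if (is.null(model_mean_area_mm2)) return(TRUE)
      a <- polygon_area(ct)
      a >= 0.25 * model_mean_area_mm2 && a <= 4 * model_mean_area_mm2
    }, logical(1)))
  base13 <- base && contours_ok
  conv <- isTRUE(all(seg$converged))
  c(m1 = base13, m2 = base13, m3 = base13, m4 = base13 && conv)
}
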