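# Tibial position by the four femoral-reference constructions, translation
# as the pre/post change, and the four technical factors. All positions are
# SIGNED, anterior-positive: a positive translation is an anterior shift of
# the tibia, which is what an ACL-deficient knee shows under posterior load
# on the femur.

#' Force line (posterior load central line) constructor
#'
#' @param skin_point mm coordinate where the plunger meets the skin.
#' @param direction unit 2-vector of the load central line (pointing
#'   anteriorly, into the limb).
#' @return Object of class `force_line`.
#' @export
force_line <- function(skin_point, direction) {
  structure(list(skin_point = as.numeric(skin_point),
                 direction = unit_vec(direction)), class = "force_line")
}

#' Tangent line to a contour in a given direction
#'
#' Among all lines with direction `direction` touching the landmark contour,
#' returns the extremal one on the requested side: for `side = "posterior"`
#' the line with the minimal anterior offset (it supports the contour from
#' the posterior). Ties between vertices are broken toward the smaller row
#' (y) coordinate.
#'
#' @param contour `k x 2` landmark matrix (mm).
#' @param direction unit 2-vector of the tangent line.
#' @param side `"posterior"` or `"anterior"`.
#' @param anterior unit 2-vector of the anterior direction (default `+x`).
#' @return list with `point` (the tangent contour vertex), `direction`,
#'   `offset` (signed anterior coordinate of the line) and `index`.
#' @export
tangent_line <- function(contour, direction, side = c("posterior", "anterior"),
                         anterior = c(1, 0)) {
  side <- match.arg(side)
  contour <- matrix(contour, ncol = 2)
  if (nrow(contour) < 3L) stop("contour needs >= 3 points")
  direction <- unit_vec(direction)
  n <- oriented_normal(direction, anterior)
  proj <- contour[, 1] * n[1] + contour[, 2] * n[2]
  if (diff(range(proj)) < 1e-9)
    stop("tangent ambiguous: contour degenerate along the given direction")
  target <- if (side == "posterior") min(proj) else max(proj)
  cand <- which(abs(proj - target) < 1e-9)
  idx <- cand[which.min(contour[cand, 2])]       # tie-break: smaller row (y)
  list(point = contour[idx, ], direction = direction,
       offset = proj[idx], index = idx)
}

# signed distance of the tibial axis from a reference point, anterior +
.position_from_point <- function(ref, tibial_axis, anterior) {
  n <- oriented_normal(tibial_axis$direction, anterior)
  sum((tibial_axis$point - ref) * n)
}

.tp_result <- function(method, reference, position, success = TRUE) {
  structure(list(method = method, reference = reference,
                 tibial_position_mm = position, success = success),
            class = "tibial_position")
}

#' @export
print.tibial_position <- function(x, ...) {
  cat(sprintf("<tibial_position> method %d: %s\n", x$method,
              if (x$success) sprintf("%+.2f mm", x$tibial_position_mm)
              else "failed"))
  invisible(x)
}

#' Tibial position, method 1 (central measurement)
#'
#' The femoral axis is intersected with the margins of the medial and
#' lateral condyle contours (taking the distal-most crossing of each), the
#' femoral reference point is the midpoint of the two intersections, and the
#' tibial position is the signed perpendicular distance from that point to
#' the tibial axis, positive when the tibial axis lies anterior.
#'
#' @param seg a `knee_seg` (or any list with `femoral_axis`, `tibial_axis`,
#'   `condyle_contours`, `anterior`).
#' @return A `tibial_position` object (`success = FALSE` when the axis
#'   misses a contour).
#' @export
tibial_position_m1 <- function(seg) {
  ant <- anterior_vec(seg$anterior)
  fa <- seg$femoral_axis
  pts <- lapply(seg$condyle_contours, function(ct)
    line_polygon_intersections(fa$point, fa$direction, ct))
  if (any(vapply(pts, nrow, integer(1)) == 0L))
    return(.tp_result(1L, NULL, NA_real_, FALSE))
  hits <- lapply(pts, function(p) p[which.max(p[, 2]), ])  # distal-most
  ref <- (hits[[1]] + hits[[2]]) / 2
  .tp_result(1L, ref, .position_from_point(ref, seg$tibial_axis, ant))
}

#' Tibial position, method 2 (combined central-peripheral measurement)
#'
#' Lines parallel to the tibial axis and tangent to the posterior margins of
#' the two condyles are drawn; the femoral reference line is their midline,
#' and the tibial position is the signed distance between that (parallel)
#' line and the tibial axis, anterior-positive.
#'
#' @inheritParams tibial_position_m1
#' @return A `tibial_position` object whose `reference` is a line.
#' @export
tibial_position_m2 <- function(seg) {
  ant <- anterior_vec(seg$anterior)
  ta <- seg$tibial_axis
  tg <- lapply(seg$condyle_contours, function(ct)
    try(tangent_line(ct, ta$direction, "posterior", ant), silent = TRUE))
  if (any(vapply(tg, inherits, logical(1), "try-error")))
    return(.tp_result(2L, NULL, NA_real_, FALSE))
  ref_offset <- (tg[[1]]$offset + tg[[2]]$offset) / 2
  n <- oriented_normal(ta$direction, ant)
  axis_offset <- sum(ta$point * n)
  ref_line <- list(offset = ref_offset, direction = ta$direction)
  .tp_result(2L, ref_line, axis_offset - ref_offset)
}

#' Tibial position, method 3 (femoral condyle tangent measurement)
#'
#' As method 2 but with tangents parallel to the *femoral* axis; the
#' reference is the midpoint of the two tangent points, and the position is
#' its signed perpendicular distance to the tibial axis.
#'
#' @inheritParams tibial_position_m1
#' @export
tibial_position_m3 <- function(seg) {
  ant <- anterior_vec(seg$anterior)
  fa <- seg$femoral_axis
  tg <- lapply(seg$condyle_contours, function(ct)
    try(tangent_line(ct, fa$direction, "posterior", ant), silent = TRUE))
  if (any(vapply(tg, inherits, logical(1), "try-error")))
    return(.tp_result(3L, NULL, NA_real_, FALSE))
  ref <- (tg[[1]]$point + tg[[2]]$point) / 2
  .tp_result(3L, ref, .position_from_point(ref, seg$tibial_axis, ant))
}

#' Tibial position, method 4 (condyle centre measurement)
#'
#' The reference is the midpoint of the centres (landmark centroids) of the
#' medial and lateral condyle model fits; requires a converged fit.
#'
#' @inheritParams tibial_position_m1
#' @export
tibial_position_m4 <- function(seg) {
  if (!is.null(seg$converged) && !all(seg$converged))
    return(.tp_result(4L, NULL, NA_real_, FALSE))
  ant <- anterior_vec(seg$anterior)
  ctr <- seg$condyle_centers
  if (is.null(ctr))
    ctr <- t(vapply(seg$condyle_contours, colMeans, numeric(2)))
  ref <- colMeans(ctr)
  .tp_result(4L, ref, .position_from_point(ref, seg$tibial_axis, ant))
}

#' Tibial translation between the unstressed and stressed views
#'
#' The change in the signed tibial position: `position(post) -
#' position(pre)`, anterior-positive. Reported as unavailable (`NA` with
#' `success = FALSE`) when either view failed quality control or the
#' method's construction failed on either view.
#'
#' @param pre,post `knee_seg` objects for the unstressed and stressed views.
#' @param method integer 1--4.
#' @param absolute return `|translation|` instead of the signed value.
#' @return list with `translation_mm`, `position_pre_mm`,
#'   `position_post_mm`, `success`.
#' @export
tibial_translation <- function(pre, post, method, absolute = FALSE) {
  f <- switch(method, tibial_position_m1, tibial_position_m2,
              tibial_position_m3, tibial_position_m4)
  qc_ok <- function(seg) is.null(seg$qc) ||
    isTRUE(seg$qc[[paste0("m", method)]])
  a <- f(pre); b <- f(post)
  ok <- a$success && b$success && qc_ok(pre) && qc_ok(post)
  tr <- if (ok) b$tibial_position_mm - a$tibial_position_mm else NA_real_
  if (ok && absolute) tr <- abs(tr)
  list(translation_mm = tr,
       position_pre_mm = if (a$success) a$tibial_position_mm else NA_real_,
       position_post_mm = if (b$success) b$tibial_position_mm else NA_real_,
       success = ok)
}

#' Knee flexion angle from the two shaft axes
#'
#' The angle between the femoral and tibial axes in the clinical convention:
#' a straight leg (axes collinear, away-directions antiparallel) measures 0
#' degrees, increasing with flexion. Value in `[0, 180)`.
#'
#' @param seg a `knee_seg` (or list with both `axis_line`s).
#' @return Angle in degrees.
#' @export
flexion_angle <- function(seg) {
  if (is.null(seg$femoral_axis) || is.null(seg$tibial_axis))
    stop("flexion angle needs both axes")
  u <- seg$femoral_axis$direction; v <- seg$tibial_axis$direction
  ang <- rad2deg(acos(pmin(pmax(sum(u * v), -1), 1)))
  180 - ang
}

#' Intercondylar distance
#'
#' Euclidean distance between the medial and lateral condyle centres
#' (landmark centroids); a projectional proxy for limb rotation during
#' imaging.
#'
#' @param seg a `knee_seg`.
#' @return Distance in mm (>= 0), or `NA` if the condyle fit failed.
#' @export
intercondylar_distance <- function(seg) {
  if (!is.null(seg$converged) && !all(seg$converged)) return(NA_real_)
  ctr <- seg$condyle_centers
  if (is.null(ctr))
    ctr <- t(vapply(seg$condyle_contours, colMeans, numeric(2)))
  sqrt(sum((ctr[1, ] - ctr[2, ])^2))
}

#' Force-joint distance and angle
#'
#' Distance: signed perpendicular distance of the force line's skin point
#' from the tibial plateau line, positive when the skin point is distal to
#' ("below") the plateau. Angle: angle between the load central line and the
#' plateau in `(-90, 90]` degrees, positive when the force direction points
#' toward the plateau.
#'
#' @param force a [force_line()].
#' @param plateau_point,plateau_dir a point on and the direction of the
#'   tibial plateau line (mm).
#' @param distal unit 2-vector pointing distally (default `+y`, i.e. down
#'   the image).
#' @return list with `distance_mm` and `angle_deg`.
#' @export
force_joint_metrics <- function(force, plateau_point, plateau_dir,
                                distal = c(0, 1)) {
  stopifnot(inherits(force, "force_line"))
  n <- oriented_normal(unit_vec(plateau_dir), distal)   # distal-positive
  dist <- sum((force$skin_point - plateau_point) * n)
  u <- force$direction
  cosang <- abs(sum(u * unit_vec(plateau_dir)))
  ang <- rad2deg(acos(pmin(pmax(cosang, -1), 1)))       # in [0, 90]
  drift <- sum(u * n)                                   # distal-ward motion
  toward <- if (dist >= 0) drift <= 0 else drift >= 0   # approaching plateau
  list(distance_mm = dist, angle_deg = if (toward) ang else -ang)
}

#' Detect the stress-device plunger rod in a phantom image
#'
#' The plunger renders as a thin rod brighter than bone entering from the
#' posterior border. Pixels above a rod-specific threshold are collected,
#' the load central line is their principal axis oriented anteriorly, and
#' the skin point is the anterior-most rod pixel.
#'
#' @param img an [image2d] (original or working resolution).
#' @return A [force_line()], or `NULL` if no rod is found.
#' @export
detect_force_marker <- function(img) {
  px <- img$pixels
  med <- stats::median(px)
  thr <- max(px) - 0.2 * (max(px) - med)
  if (max(px) - med < 1e-6) return(NULL)
  idx <- which(px > thr, arr.ind = TRUE)
  if (nrow(idx) < 10L) return(NULL)
  pts <- px_to_mm(img, idx[, 1], idx[, 2])
  ctr <- colMeans(pts)
  ev <- eigen(crossprod(sweep(pts, 2, ctr)), symmetric = TRUE)
  dir <- ev$vectors[, 1]
  ant <- anterior_vec(img)
  if (sum(dir * ant) < 0) dir <- -dir
  proj <- (pts[, 1] - ctr[1]) * dir[1] + (pts[, 2] - ctr[2]) * dir[2]
  tip <- pts[which.max(proj), ]
  force_line(tip, dir)
}
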