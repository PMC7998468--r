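#' Specification of a stress-radiograph phantom
#'
#' Describes a simplified lateral knee view: a tilted femoral shaft ending in
#' two overlapping near-circular condyles, a vertical tibial shaft separated
#' from them by a radiolucent joint gap, and a bright thin rod mimicking the
#' stress-device plunger that defines the posterior load central line. The
#' stressed view of a pair is the same scene with the whole tibia rigidly
#' shifted by `tibial_translation_mm` along the anterior direction, which is
#' the `+col` axis in the phantom frame.
#'
#' Defaults are sized so an 8--14 cm shaft band fits on both sides of the
#' joint and, where a population value is known for the imaging protocol,
#' follow it (30 degrees flexion, force line 39.7 mm distal to the plateau at
#' -10.58 degrees, condyle centre offset of norm 4.53 mm).
#'
#' @param image_height_px,image_width_px raster size in pixels.
#' @param pixel_spacing_mm isotropic pixel spacing (mm/px).
#' @param femoral_shaft_width_mm,tibial_shaft_width_mm shaft widths.
#' @param condyle_radii_mm length-2 (medial, lateral) condyle radii in mm.
#' @param condyle_center_offset_mm 2-vector from the medial to the lateral
#'   condyle centre (projectional rotation proxy); its norm is the true
#'   intercondylar distance.
#' @param condyle_eccentricity length-2 ratio of the condyle's vertical to
#'   horizontal semi-axis (1 = circle).
#' @param joint_gap_mm radiolucent gap between condyles and tibial plateau.
#' @param flexion_angle_deg tilt of the femoral shaft away from the tibial
#'   axis; the tibia stays vertical so that an anterior shift changes the
#'   tibial-axis distance by exactly the shift.
#' @param tibial_translation_mm signed anterior shift of the tibia between
#'   the two views of a pair (anterior-positive).
#' @param force_joint_distance_mm,force_joint_angle_deg placement of the
#'   plunger rod: signed distance of the skin point distal (+) to the tibial
#'   plateau, and signed angle of the load line to the plateau (positive =
#'   pointing toward the plateau). Used to derive `force_line_skin_point` /
#'   `force_line_direction` when those are not given explicitly.
#' @param force_line_skin_point,force_line_direction explicit rod geometry
#'   (mm point, unit 2-vector), overriding the two scalars above.
#' @param noise_sd additive Gaussian gray-level noise (0 = noise free).
#' @param background_level,bone_level gray levels of soft tissue and bone.
#' @param seed integer seed; rendering is a pure function of (spec, seed).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_height_px = 640L, image_width_px = 420L,
                         pixel_spacing_mm = 0.5,
                         femoral_shaft_width_mm = 28,
                         tibial_shaft_width_mm = 26,
                         condyle_radii_mm = c(medial = 19, lateral = 22),
                         condyle_center_offset_mm = c(4.2, 1.7),
                         condyle_eccentricity = c(1, 1),
                         joint_gap_mm = 6,
                         flexion_angle_deg = 30,
                         tibial_translation_mm = 0,
                         force_joint_distance_mm = 39.7,
                         force_joint_angle_deg = -10.58,
                         force_line_skin_point = NULL,
                         force_line_direction = NULL,
                         noise_sd = 0,
                         background_level = 60, bone_level = 160,
                         seed = 1L) {
  stopifnot_scalar(pixel_spacing_mm, "pixel_spacing_mm", positive = TRUE)
  stopifnot_scalar(joint_gap_mm, "joint_gap_mm", positive = TRUE)
  if (length(condyle_radii_mm) != 2L || any(condyle_radii_mm <= 0))
    stop("'condyle_radii_mm' must be two positive radii")
  if (bone_level <= background_level)
    stop("'bone_level' must exceed 'background_level'")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  spec <- structure(list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    pixel_spacing_mm = pixel_spacing_mm,
    femoral_shaft_width_mm = femoral_shaft_width_mm,
    tibial_shaft_width_mm = tibial_shaft_width_mm,
    condyle_radii_mm = unname(condyle_radii_mm),
    condyle_center_offset_mm = as.numeric(condyle_center_offset_mm),
    condyle_eccentricity = as.numeric(condyle_eccentricity),
    joint_gap_mm = joint_gap_mm,
    flexion_angle_deg = flexion_angle_deg,
    tibial_translation_mm = tibial_translation_mm,
    force_joint_distance_mm = force_joint_distance_mm,
    force_joint_angle_deg = force_joint_angle_deg,
    force_line_skin_point = force_line_skin_point,
    force_line_direction = force_line_direction,
    noise_sd = noise_sd,
    background_level = background_level, bone_level = bone_level,
    seed = as.integer(seed)), class = "phantom_spec")
  # the shaft-axis fit needs up to 14 cm of shaft on each side of the joint
  height_mm <- spec$image_height_px * pixel_spacing_mm
  need_mm <- 2 * (140 + 2 * pixel_spacing_mm) + joint_gap_mm
  if (height_mm < need_mm)
    stop(sprintf(
      "image too small for the 8-14 cm shaft band: height %.0f mm < required %.0f mm (>= %d px at %.3g mm/px)",
      height_mm, need_mm, ceiling(need_mm / pixel_spacing_mm),
      pixel_spacing_mm))
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %dx%d px @ %.3g mm/px, flexion %.1f deg, translation %+.2f mm, noise sd %.3g, seed %d\n",
    x$image_height_px, x$image_width_px, x$pixel_spacing_mm,
    x$flexion_angle_deg, x$tibial_translation_mm, x$noise_sd, x$seed))
  invisible(x)
}

# Scene geometry shared by both views (mm frame, origin at pixel (1,1)).
phantom_scene <- function(spec) {
  h_mm <- (spec$image_height_px - 1) * spec$pixel_spacing_mm
  w_mm <- (spec$image_width_px - 1) * spec$pixel_spacing_mm
  joint <- c(0.57 * w_mm, 0.5 * h_mm)                # joint centre
  phi <- deg2rad(spec$flexion_angle_deg)
  u_f <- c(-sin(phi), -cos(phi))                     # femoral axis, away
  u_t <- c(0, 1)                                     # tibial axis, away
  r <- spec$condyle_radii_mm
  rbar <- mean(r)
  d_c <- (rbar + spec$joint_gap_mm / 2) / cos(phi)   # condyle centre depth
  c0 <- joint + d_c * u_f
  off <- spec$condyle_center_offset_mm
  centers <- rbind(medial = c0 - off / 2, lateral = c0 + off / 2)
  y_plateau <- joint[2] + spec$joint_gap_mm / 2
  # plunger rod
  skin <- spec$force_line_skin_point
  fdir <- spec$force_line_direction
  if (is.null(skin))
    skin <- c(joint[1] - spec$tibial_shaft_width_mm / 2 - 22,
              y_plateau + spec$force_joint_distance_mm)
  if (is.null(fdir)) {
    a <- deg2rad(spec$force_joint_angle_deg)
    # anterior-pointing; negative angle = moving away from the plateau (down)
    fdir <- c(cos(a), -sin(a) * sign(spec$force_joint_distance_mm + 1e-12))
  }
  fdir <- unit_vec(fdir)
  list(joint = joint, u_f = u_f, u_t = u_t, centers = centers,
       y_plateau = y_plateau, skin = skin, fdir = fdir,
       h_mm = h_mm, w_mm = w_mm)
}

# Closed condyle contour as k landmarks at fixed angular parameters
# (correspondence by angle index across phantoms).
condyle_contour <- function(center, radius, ecc, k = 32L) {
  th <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  cbind(center[1] + radius * cos(th), center[2] + radius * ecc * sin(th))
}

# -- rendering primitives: coverage in [0,1] with ~1 px soft edge ----------
.coverage <- function(signed_dist_mm, edge_mm) {
  pmin(pmax(0.5 - signed_dist_mm / edge_mm, 0), 1)
}

render_phantom_view <- function(spec, scene, tibia_shift_mm) {
  s <- spec$pixel_spacing_mm
  edge <- s                                           # soft-edge width
  x <- (seq_len(spec$image_width_px) - 1) * s
  y <- (seq_len(spec$image_height_px) - 1) * s
  X <- matrix(x, nrow = length(y), ncol = length(x), byrow = TRUE)
  Y <- matrix(y, nrow = length(y), ncol = length(x))
  bg <- spec$background_level
  bone_add <- spec$bone_level - bg
  img <- matrix(bg, length(y), length(x))

  # femoral shaft: band around the femoral axis from the condyle centres up
  jp <- scene$joint; u <- scene$u_f
  tx <- X - jp[1]; ty <- Y - jp[2]
  perp <- tx * -u[2] + ty * u[1]                     # across-axis coordinate
  along <- tx * u[1] + ty * u[2]                     # away from joint
  t0 <- sqrt(sum((scene$centers[1, ] + scene$centers[2, ] - 2 * jp)^2)) / 2
  d_shaft <- pmax(abs(perp) - spec$femoral_shaft_width_mm / 2, t0 - along)
  img <- img + bone_add * .coverage(d_shaft, edge)

  # tibia: vertical rectangle, rigidly shifted in the stressed view
  xt <- jp[1] + tibia_shift_mm
  d_tib <- pmax(abs(X - xt) - spec$tibial_shaft_width_mm / 2,
                scene$y_plateau - Y)
  img <- img + bone_add * .coverage(d_tib, edge)

  # condyles: additive, like summation of projected densities, so the rim of
  # the smaller condyle stays visible inside the larger one
  for (i in 1:2) {
    ci <- scene$centers[i, ]; r <- spec$condyle_radii_mm[i]
    ecc <- spec$condyle_eccentricity[i]
    rn <- sqrt(((X - ci[1]) / r)^2 + ((Y - ci[2]) / (r * ecc))^2)
    d_cond <- (rn - 1) * r * min(1, ecc)
    img <- img + 0.55 * bone_add * .coverage(d_cond, edge)
  }

  # plunger rod: bright capsule from the posterior border to the skin point
  p1 <- c(0, scene$skin[2] + (scene$skin[1] - 0) *
            (-scene$fdir[2] / scene$fdir[1]))
  p0 <- scene$skin
  seg <- p0 - p1; L2 <- sum(seg^2)
  tt <- pmin(pmax(((X - p1[1]) * seg[1] + (Y - p1[2]) * seg[2]) / L2, 0), 1)
  d_rod <- sqrt((X - (p1[1] + tt * seg[1]))^2 +
                (Y - (p1[2] + tt * seg[2]))^2) - 1.25
  # metal plunger: rendered brighter than any bone summation so the force
  # marker is separable by intensity alone
  img <- img + 3 * bone_add * .coverage(d_rod, edge)
  img
}

#' Render a pre/post stress phantom pair with ground truth
#'
#' Renders two radiograph-like rasters that differ only by a rigid anterior
#' shift of the tibia (the applied "translation") plus independent noise
#' realizations, and returns the exact scene geometry as ground truth: an
#' oracle for every segmentation and measurement stage.
#'
#' @param spec a [phantom_spec].
#' @return A list with elements `pre`, `post` (both [image2d]) and `truth`,
#'   a `ground_truth` list carrying the joint row, both axes, condyle
#'   contours and centres (for each view where they differ), the applied
#'   translation and the true technical factors.
#' @export
render_phantom_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  scene <- phantom_scene(spec)
  s <- spec$pixel_spacing_mm
  pre_px <- render_phantom_view(spec, scene, 0)
  post_px <- render_phantom_view(spec, scene, spec$tibial_translation_mm)
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed, list(
      matrix(stats::rnorm(length(pre_px), 0, spec$noise_sd), nrow(pre_px)),
      matrix(stats::rnorm(length(post_px), 0, spec$noise_sd), nrow(post_px))))
    pre_px <- pre_px + noise[[1]]
    post_px <- post_px + noise[[2]]
  }
  contours <- list(
    medial = condyle_contour(scene$centers[1, ], spec$condyle_radii_mm[1],
                             spec$condyle_eccentricity[1]),
    lateral = condyle_contour(scene$centers[2, ], spec$condyle_radii_mm[2],
                              spec$condyle_eccentricity[2]))
  truth <- structure(list(
    joint_row_px = scene$joint[2] / s + 1,
    femoral_axis = axis_line(scene$joint, scene$u_f, "femoral"),
    tibial_axis_pre = axis_line(scene$joint, scene$u_t, "tibial"),
    tibial_axis_post = axis_line(
      scene$joint + c(spec$tibial_translation_mm, 0), scene$u_t, "tibial"),
    condyle_contours = contours,
    condyle_centers = scene$centers,
    plateau_point = c(scene$joint[1], scene$y_plateau),
    plateau_dir = c(1, 0),
    force_line = force_line(scene$skin, scene$fdir),
    true_translation_mm = spec$tibial_translation_mm,
    true_flexion_deg = spec$flexion_angle_deg,
    true_force_joint_distance_mm = scene$skin[2] - scene$y_plateau,
    true_force_joint_angle_deg = spec$force_joint_angle_deg,
    true_intercondylar_mm = sqrt(sum(spec$condyle_center_offset_mm^2))),
    class = "ground_truth")
  list(pre = image2d(pre_px, s, anterior = "+col"),
       post = image2d(post_px, s, anterior = "+col"),
       truth = truth)
}

#' Write a phantom pair to disk
#'
#' Writes the two views as PNG with YAML sidecars and the ground truth as
#' JSON next to them.
#'
#' @param pair result of [render_phantom_pair()].
#' @param dir output directory (created if needed).
#' @param basename file stem; files are `<stem>_pre.png`, `<stem>_post.png`,
#'   `<stem>_truth.json`.
#' @return The three paths, invisibly.
#' @export
write_phantom_pair <- function(pair, dir, basename = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- max(pair$pre$pixels, pair$post$pixels)
  p1 <- file.path(dir, paste0(basename, "_pre.png"))
  p2 <- file.path(dir, paste0(basename, "_post.png"))
  p3 <- file.path(dir, paste0(basename, "_truth.json"))
  write_image2d(pair$pre, p1, intensity_scale = scale)
  write_image2d(pair$post, p2, intensity_scale = scale)
  tr <- pair$truth
  jsonlite::write_json(list(
    joint_row_px = tr$joint_row_px,
    femoral_axis = unclass(tr$femoral_axis),
    tibial_axis_pre = unclass(tr$tibial_axis_pre),
    tibial_axis_post = unclass(tr$tibial_axis_post),
    condyle_centers = tr$condyle_centers,
    condyle_contours = lapply(tr$condyle_contours, unname),
    true_translation_mm = tr$true_translation_mm,
    true_flexion_deg = tr$true_flexion_deg,
    true_force_joint_distance_mm = tr$true_force_joint_distance_mm,
    true_force_joint_angle_deg = tr$true_force_joint_angle_deg,
    true_intercondylar_mm = tr$true_intercondylar_mm),
    p3, auto_unbox = TRUE, digits = NA)
  invisible(c(pre = p1, post = p2, truth = p3))
}
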