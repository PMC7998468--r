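# End-to-end orchestration: configuration, one-view segmentation, and
# pre/post pair measurement producing a per-patient record.

#' Pipeline configuration
#'
#' All tunable parameters of the measurement pipeline in one validated,
#' serializable list. Defaults are working values at half resolution
#' (down-sampling factor 2).
#'
#' @param downsample_factor,sigma_px preprocessing (see [preprocess()]).
#' @param alpha,beta,max_step,corridor_px edge-path cost weights: intensity
#'   weight, column-step penalty per px, maximum step per row, and the
#'   half-width of the search corridor around the tracked bone boundary.
#' @param band_mm shaft-axis fitting band, mm from the joint space.
#' @param roi_size_mm condyle region-of-interest side length.
#' @param asm_search_px,asm_tol_px,asm_max_iter,asm_clamp_sd,asm_var_keep,
#'   asm_min_contrast_frac condyle model fit: normal search half-range,
#'   convergence tolerance (mean landmark move, px), iteration cap, shape
#'   coefficient clamp (standard deviations), retained variance fraction,
#'   and the minimum inside-outside contrast (fraction of the image's
#'   robust intensity range) for a fit to count as converged.
#' @param condyle_offset_prior,condyle_radius_prior,joint_gap_prior
#'   initialization priors: expected medial-to-lateral centre offset (mm),
#'   expected radii (medial, lateral; mm) and joint gap (mm).
#' @param ci_denominator,t_var_equal statistics conventions (see
#'   [diag_performance()], [two_sample_t()]).
#' @param seed default seed for stochastic helpers.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(downsample_factor = 2L, sigma_px = 1.5,
                       alpha = 1, beta = 0.25, max_step = 3L,
                       corridor_px = 6L,
                       band_mm = c(80, 140), roi_size_mm = 100,
                       asm_search_px = 4L, asm_tol_px = 0.1,
                       asm_max_iter = 50L, asm_clamp_sd = 3,
                       asm_var_keep = 0.95, asm_min_contrast_frac = 0.08,
                       condyle_offset_prior = c(4.2, 1.7),
                       condyle_radius_prior = c(19, 22),
                       joint_gap_prior = 6,
                       ci_denominator = "total", t_var_equal = FALSE,
                       seed = 1L) {
  cfg <- structure(list(
    downsample_factor = as.integer(downsample_factor), sigma_px = sigma_px,
    alpha = alpha, beta = beta, max_step = as.integer(max_step),
    corridor_px = as.integer(corridor_px),
    band_mm = as.numeric(band_mm), roi_size_mm = roi_size_mm,
    asm_search_px = as.integer(asm_search_px), asm_tol_px = asm_tol_px,
    asm_max_iter = as.integer(asm_max_iter), asm_clamp_sd = asm_clamp_sd,
    asm_var_keep = asm_var_keep,
    asm_min_contrast_frac = asm_min_contrast_frac,
    condyle_offset_prior = as.numeric(condyle_offset_prior),
    condyle_radius_prior = as.numeric(condyle_radius_prior),
    joint_gap_prior = joint_gap_prior,
    ci_denominator = ci_denominator, t_var_equal = t_var_equal,
    seed = as.integer(seed)), class = "run_config")
  validate_config(cfg)
}

#' @rdname run_config
#' @param cfg a `run_config` list to validate.
#' @export
validate_config <- function(cfg) {
  with(cfg, {
    if (downsample_factor < 1L) stop("downsample_factor must be >= 1")
    if (sigma_px < 0) stop("sigma_px must be >= 0")
    if (alpha < 0 || beta < 0) stop("cost weights must be >= 0")
    if (max_step < 1L) stop("max_step must be >= 1")
    if (length(band_mm) != 2L || band_mm[1] <= 0 || band_mm[2] <= band_mm[1])
      stop("band_mm must be an increasing positive pair")
    if (asm_search_px < 1L || asm_max_iter < 1L || asm_clamp_sd <= 0)
      stop("invalid condyle-fit parameters")
    if (asm_var_keep <= 0 || asm_var_keep > 1)
      stop("asm_var_keep must be in (0, 1]")
  })
  cfg
}

#' Read / write a run configuration
#'
#' Round-trips the flat configuration through YAML losslessly.
#'
#' @param path YAML file path.
#' @param cfg a [run_config()].
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Segment one lateral knee radiograph
#'
#' Runs the full single-view chain: preprocessing, joint-row localization,
#' anterior/posterior edge paths for femur and tibia, shaft-axis fits,
#' condyle ROI, condyle model fit, tibial-plateau line (through the
#' most-proximal points of the tibial edge paths) and quality-control
#' flags.
#'
#' @param img an [image2d] at acquisition resolution.
#' @param config a [run_config()].
#' @param model condyle model; defaults to [default_condyle_model()].
#' @return Object of class `knee_seg` with elements `joint_row_px`
#'   (original-resolution row), `edges`, `femoral_axis`, `tibial_axis`,
#'   `condyle_contours`, `condyle_centers`, `converged`, `plateau_point`,
#'   `plateau_dir`, `qc`, `anterior`, `spacing_mm`, `extent_mm`.
#' @export
segment_knee <- function(img, config = run_config(),
                         model = default_condyle_model(params = config)) {
  stopifnot(inherits(img, "image2d"))
  wrk <- preprocess(img, config$downsample_factor, config$sigma_px)
  joint_row <- locate_joint_row(wrk)
  fem <- segment_bone_edges(wrk, joint_row, "femur", config)
  tib <- segment_bone_edges(wrk, joint_row, "tibia", config)
  femoral_axis <- fit_axis(fem$anterior, fem$posterior, joint_row,
                           wrk$spacing_mm, config$band_mm, wrk$origin_mm)
  tibial_axis <- fit_axis(tib$anterior, tib$posterior, joint_row,
                          wrk$spacing_mm, config$band_mm, wrk$origin_mm)
  roi <- define_condyle_roi(joint_row, femoral_axis, wrk, config$roi_size_mm)
  cond <- segment_condyles(wrk, roi, model, config, joint_row = joint_row)
  # tibial plateau: line through the most-proximal anterior and posterior
  # tibial edge points (replaceable strategy)
  top_a <- tib$anterior[which.min(tib$anterior$row), ]
  top_p <- tib$posterior[which.min(tib$posterior$row), ]
  pa <- px_to_mm(wrk, top_a$row, top_a$col)[1, ]
  pp <- px_to_mm(wrk, top_p$row, top_p$col)[1, ]
  plateau_dir <- if (sum(abs(pa - pp)) < 1e-9) c(1, 0) else unit_vec(pa - pp)
  nr_mm <- px_to_mm(img, nrow(img$pixels), ncol(img$pixels))[1, ]
  seg <- structure(list(
    joint_row_px = (joint_row - 1) * config$downsample_factor + 1,
    joint_row_working = joint_row,
    edges = list(femur_anterior = fem$anterior,
                 femur_posterior = fem$posterior,
                 tibia_anterior = tib$anterior,
                 tibia_posterior = tib$posterior),
    femoral_axis = femoral_axis, tibial_axis = tibial_axis,
    condyle_contours = list(medial = cond$medial$landmarks,
                            lateral = cond$lateral$landmarks),
    condyle_centers = rbind(medial = cond$medial$center,
                            lateral = cond$lateral$center),
    converged = c(medial = cond$medial$converged,
                  lateral = cond$lateral$converged),
    plateau_point = (pa + pp) / 2, plateau_dir = plateau_dir,
    anterior = img$anterior, spacing_mm = img$spacing_mm,
    model_mean_area_mm2 = model_mean_area(model),
    extent_mm = c(img$origin_mm[1], nr_mm[1], img$origin_mm[2], nr_mm[2])),
    class = "knee_seg")
  seg$qc <- qc_segmentation(seg)
  seg
}

#' @export
print.knee_seg <- function(x, ...) {
  cat(sprintf("<knee_seg> joint row %.0f px; qc: %s\n", x$joint_row_px,
              paste(sprintf("m%d=%s", 1:4, ifelse(x$qc, "ok", "FAIL")),
                    collapse = " ")))
  print(x$femoral_axis); print(x$tibial_axis)
  invisible(x)
}

#' Overlay plot of a segmentation for review
#'
#' @param x a `knee_seg`.
#' @param img the [image2d] it was computed from.
#' @param ... passed to [plot.image2d()].
#' @export
plot.knee_seg <- function(x, img = NULL, ...) {
  if (is.null(img)) stop("supply the image the segmentation came from")
  op <- graphics::par(mar = c(0, 0, 0, 0)); on.exit(graphics::par(op))
  plot(img, ...)
  nr <- nrow(img$pixels); nc <- ncol(img$pixels); s <- img$spacing_mm
  to_xy <- function(pts_mm) {
    rc <- mm_to_px(img, pts_mm[, 1], pts_mm[, 2])
    cbind((rc[, 2] - 1) / (nc - 1), 1 - (rc[, 1] - 1) / (nr - 1))
  }
  for (ct in x$condyle_contours) {
    xy <- to_xy(rbind(ct, ct[1, ]))
    graphics::lines(xy[, 1], xy[, 2], col = "yellow")
  }
  for (ax in list(x$femoral_axis, x$tibial_axis)) {
    tt <- seq(-150, 150, by = 5)
    pts <- cbind(ax$point[1] + tt * ax$direction[1],
                 ax$point[2] + tt * ax$direction[2])
    xy <- to_xy(pts)
    graphics::lines(xy[, 1], xy[, 2], col = "cyan")
  }
  invisible(x)
}

#' Measure a pre/post stress radiograph pair
#'
#' Segments both views, computes the tibial position by all four methods in
#' each, the translations (post minus pre, anterior-positive), and the four
#' technical factors on the stressed view. The force line is auto-detected
#' from the plunger marker unless given.
#'
#' @param pre,post [image2d] unstressed and stressed views.
#' @param config a [run_config()].
#' @param force a [force_line()] (mm), or `NULL` to auto-detect in `post`.
#' @param model condyle model; default trained from synthetic phantoms.
#' @param id patient identifier carried into the record.
#' @return Object of class `patient_record`: per-method translations and
#'   success flags, positions pre/post, technical factors, and the two
#'   `knee_seg` objects.
#' @export
measure_knee_pair <- function(pre, post, config = run_config(),
                              force = NULL,
                              model = default_condyle_model(params = config),
                              id = "case") {
  seg_pre <- segment_knee(pre, config, model)
  seg_post <- segment_knee(post, config, model)
  meth <- lapply(1:4, function(m) tibial_translation(seg_pre, seg_post, m))
  names(meth) <- paste0("m", 1:4)
  if (is.null(force)) force <- detect_force_marker(post)
  fj <- if (!is.null(force))
    force_joint_metrics(force, seg_post$plateau_point, seg_post$plateau_dir)
  else list(distance_mm = NA_real_, angle_deg = NA_real_)
  structure(list(
    id = id,
    translation_mm = vapply(meth, `[[`, numeric(1), "translation_mm"),
    position_pre_mm = vapply(meth, `[[`, numeric(1), "position_pre_mm"),
    position_post_mm = vapply(meth, `[[`, numeric(1), "position_post_mm"),
    success = vapply(meth, `[[`, logical(1), "success"),
    flexion_deg = tryCatch(flexion_angle(seg_post), error = function(e) NA_real_),
    intercondylar_mm = intercondylar_distance(seg_post),
    fj_dist_mm = fj$distance_mm, fj_angle_deg = fj$angle_deg,
    seg_pre = seg_pre, seg_post = seg_post), class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s\n", x$id))
  for (m in 1:4)
    cat(sprintf("  method %d: %s\n", m,
                if (x$success[m]) sprintf("%+.2f mm", x$translation_mm[m])
                else "unavailable"))
  cat(sprintf("  flexion %.1f deg, intercondylar %.2f mm, force-joint %.1f mm / %.1f deg\n",
              x$flexion_deg, x$intercondylar_mm, x$fj_dist_mm, x$fj_angle_deg))
  invisible(x)
}

#' Write a patient record as JSON
#'
#' @param record a `patient_record`.
#' @param path output path.
#' @export
write_patient_record <- function(record, path) {
  jsonlite::write_json(list(
    id = record$id,
    translation_mm = as.list(record$translation_mm),
    position_pre_mm = as.list(record$position_pre_mm),
    position_post_mm = as.list(record$position_post_mm),
    success = as.list(record$success),
    flexion_deg = record$flexion_deg,
    intercondylar_mm = record$intercondylar_mm,
    fj_dist_mm = record$fj_dist_mm, fj_angle_deg = record$fj_angle_deg,
    qc_pre = as.list(record$seg_pre$qc), qc_post = as.list(record$seg_post$qc)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
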