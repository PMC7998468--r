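# Point-distribution model of the femoral condyle contour and its
# active-shape-model fit. One model covers both condyles: on a lateral view
# the medial and lateral contours are the same anatomical family seen in
# projection.

# optimal rotation R (2x2, det +1) with A %*% R ~ B, both centred
procrustes_rotation <- function(A, B) {
  sv <- svd(crossprod(A, B))
  u <- sv$u; v <- sv$v
  if (det(u %*% t(v)) < 0) u[, 2] <- -u[, 2]
  u %*% t(v)
}

# outward normals of a closed landmark polyline (k x 2)
contour_normals <- function(X) {
  k <- nrow(X)
  nxt <- X[c(2:k, 1), ]; prv <- X[c(k, 1:(k - 1)), ]
  tg <- nxt - prv
  n <- cbind(-tg[, 2], tg[, 1])
  n <- n / sqrt(rowSums(n^2))
  ctr <- colMeans(X)
  flip <- rowSums(n * sweep(X, 2, ctr)) < 0
  n[flip, ] <- -n[flip, ]
  n
}

#' Train a condyle point-distribution model
#'
#' Aligns the training contours by generalized Procrustes analysis
#' (translation, rotation and scale removed), computes the mean shape and
#' the principal modes of shape variation retained to the requested
#' cumulative variance, and averages the per-landmark appearance profiles
#' (gray-value profiles along the outward contour normal) when supplied.
#'
#' @param contours list of `k x 2` landmark matrices in corresponding order.
#' @param profiles optional list (same length) of `k x L` matrices of
#'   gray-value profiles sampled along each landmark's outward normal.
#' @param var_keep cumulative variance fraction to retain (default 0.95).
#' @return An object of class `condyle_model`: `mean_shape` (`k x 2`,
#'   centred, unit centroid size), `modes` (`2k x m`, orthonormal),
#'   `variances` (length `m`, non-increasing), `appearance` (`k x L` mean
#'   profile or `NULL`), `k`, `mean_scale` (mean centroid size, mm),
#'   `mean_area_mm2`.
#' @export
train_condyle_model <- function(contours, profiles = NULL, var_keep = 0.95) {
  if (!is.list(contours) || length(contours) < 2L)
    stop("need at least 2 training contours")
  ks <- vapply(contours, nrow, integer(1))
  if (length(unique(ks)) != 1L)
    stop("training contours have inconsistent landmark counts")
  k <- ks[1]
  scales <- vapply(contours, function(ct) {
    sqrt(sum(scale(ct, scale = FALSE)^2))
  }, numeric(1))
  norm_shape <- function(ct) {
    cc <- scale(ct, scale = FALSE)
    cc / sqrt(sum(cc^2))
  }
  shapes <- lapply(contours, norm_shape)
  mean_sh <- shapes[[1]]
  for (iter in 1:4) {                          # generalized Procrustes
    shapes <- lapply(shapes, function(sh) sh %*% procrustes_rotation(sh, mean_sh))
    mean_sh <- norm_shape(Reduce(`+`, shapes) / length(shapes))
  }
  X <- t(vapply(shapes, as.vector, numeric(2 * k)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  total <- sum(Xc^2) / max(1, nrow(X) - 1)
  if (total < 1e-12) {
    modes <- matrix(numeric(0), nrow = 2 * k, ncol = 0)
    vars <- numeric(0)
  } else {
    sv <- svd(Xc)
    vars <- sv$d^2 / (nrow(X) - 1)
    keep <- which(cumsum(vars) / sum(vars) >= var_keep)[1]
    keep <- min(keep, sum(vars > 1e-10 * vars[1]))
    modes <- sv$v[, seq_len(keep), drop = FALSE]
    vars <- vars[seq_len(keep)]
  }
  app <- NULL
  if (!is.null(profiles)) {
    if (length(profiles) != length(contours))
      stop("'profiles' must match 'contours' in length")
    app <- Reduce(`+`, profiles) / length(profiles)
  }
  structure(list(
    mean_shape = matrix(mu, ncol = 2), modes = modes, variances = vars,
    appearance = app, k = k, mean_scale = mean(scales),
    mean_area_mm2 = mean(vapply(contours, polygon_area, numeric(1)))),
    class = "condyle_model")
}

#' @export
print.condyle_model <- function(x, ...) {
  cat(sprintf(
    "<condyle_model> %d landmarks, %d mode(s), mean area %.1f mm^2%s\n",
    x$k, length(x$variances), x$mean_area_mm2,
    if (is.null(x$appearance)) "" else
      sprintf(", appearance profiles of length %d", ncol(x$appearance))))
  invisible(x)
}

# pose application/inversion: x_img = s * x_model %*% t(R) + t
pose_apply <- function(shape, s, R, t) {
  sweep(s * shape %*% t(R), 2, t, `+`)
}

# least-squares similarity pose aligning `shape` (centred model frame) to Y
pose_fit <- function(shape, Y) {
  tY <- colMeans(Y)
  Yc <- sweep(Y, 2, tY)
  R <- procrustes_rotation(shape, Yc)          # shape %*% R ~ Yc
  s <- sum((shape %*% R) * Yc) / sum(shape^2)
  list(s = s, R = t(R), t = tY)                # stored so pose_apply works
}

# sample appearance profiles (k x L) along outward normals at `X` (mm)
sample_profiles <- function(img, X, normals, L, step_mm) {
  h <- (L - 1) / 2
  offs <- seq(-h, h) * step_mm
  k <- nrow(X)
  px <- rep(X[, 1], times = L) + rep(offs, each = k) * rep(normals[, 1], times = L)
  py <- rep(X[, 2], times = L) + rep(offs, each = k) * rep(normals[, 2], times = L)
  rc <- mm_to_px(img, px, py)
  matrix(bilinear_sample(img$pixels, rc[, 1], rc[, 2]), nrow = k)
}

# Fit the model to one condyle by iterative appearance matching along the
# landmark normals plus projection onto the shape space.
fit_condyle_asm <- function(img, model, center_init, scale_init,
                            params = run_config()) {
  k <- model$k
  L <- if (!is.null(model$appearance)) ncol(model$appearance) else 11L
  step_mm <- img$spacing_mm
  S <- params$asm_search_px
  tol_mm <- params$asm_tol_px * img$spacing_mm
  b <- rep(0, length(model$variances))
  pose <- list(s = scale_init, R = diag(2), t = center_init)
  shape_of <- function(b) {
    v <- as.vector(model$mean_shape)
    if (length(b)) v <- v + as.vector(model$modes %*% b)
    matrix(v, ncol = 2)
  }
  X <- pose_apply(shape_of(b), pose$s, pose$R, pose$t)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(params$asm_max_iter)) {
    nrm <- contour_normals(X)
    # all candidate displacements at once: profiles at shifts -S..S
    best_d <- numeric(k)
    costs <- matrix(NA_real_, k, 2L * S + 1L)
    for (j in seq(-S, S)) {
      Xd <- X + j * step_mm * nrm
      prof <- sample_profiles(img, Xd, nrm, L, step_mm)
      ref <- if (!is.null(model$appearance)) model$appearance else
        matrix(rep(seq(1, 0, length.out = L), each = k), nrow = k)
      costs[, j + S + 1L] <- rowSums((prof - ref)^2)
    }
    idx <- max.col(-costs, ties.method = "first")
    cl <- pmax(idx - 1L, 1L); cr <- pmin(idx + 1L, 2L * S + 1L)
    i <- seq_len(k)
    off <- parabolic_peak_offset(-costs[cbind(i, cl)], -costs[cbind(i, idx)],
                                 -costs[cbind(i, cr)])
    best_d <- (idx - S - 1L + off) * step_mm
    Y <- X + best_d * nrm
    pose <- pose_fit(shape_of(b), Y)
    z <- sweep(Y, 2, pose$t) %*% pose$R / pose$s   # back to model frame
    if (length(model$variances)) {
      b <- as.vector(crossprod(model$modes,
                               as.vector(z) - as.vector(model$mean_shape)))
      lim <- params$asm_clamp_sd * sqrt(model$variances)
      b <- pmin(pmax(b, -lim), lim)
    }
    X_new <- pose_apply(shape_of(b), pose$s, pose$R, pose$t)
    move <- mean(sqrt(rowSums((X_new - X)^2)))
    X <- X_new
    if (move < tol_mm) { converged <- TRUE; break }
  }
  # a fit locked onto structure must straddle a real edge: compare mean gray
  # just inside vs just outside the contour
  nrm <- contour_normals(X)
  inner <- sample_profiles(img, X - 2 * step_mm * nrm, nrm, 1L, step_mm)
  outer <- sample_profiles(img, X + 2 * step_mm * nrm, nrm, 1L, step_mm)
  rng <- stats::quantile(img$pixels, c(0.2, 0.98))
  contrast_ok <- mean(inner - outer) >
    params$asm_min_contrast_frac * diff(unname(rng))
  list(landmarks = X, center = colMeans(X), b = b,
       converged = converged && contrast_ok, iterations = it)
}

#' Segment both femoral condyles with the shape model
#'
#' Fits the point-distribution model twice (medial then lateral) inside the
#' condylar region of interest: at each iteration every landmark moves along
#' its outward normal to the best appearance-profile match, the similarity
#' pose is re-estimated, and the shape residual is projected onto the
#' model's modes with coefficients clamped to `+/- 3` standard deviations.
#' Initialization uses the condylar bright-mass centroid plus configurable
#' prior offsets and radii for the two condyles.
#'
#' Non-convergence (or a fit that does not straddle a real intensity edge,
#' e.g. in a blank ROI) is reported through the `converged` flags rather
#' than as an error, so quality control can veto the condyle-based methods.
#'
#' @param img working-resolution [image2d].
#' @param roi region from [define_condyle_roi()].
#' @param model a [train_condyle_model()] result (shared by both condyles)
#'   or a `condyle_model_pair` with side-specific appearance (the default
#'   pipeline model; see [default_condyle_model()]).
#' @param params see [run_config()]; uses the `asm_*` and `condyle_*_prior`
#'   entries.
#' @param joint_row joint row (working resolution), for the initialization.
#' @return list with `medial` and `lateral` fits (each: `landmarks` k x 2 mm,
#'   `center`, `b`, `converged`, `iterations`).
#' @export
segment_condyles <- function(img, roi, model, params = run_config(),
                             joint_row = NULL) {
  models <- if (inherits(model, "condyle_model_pair")) model
            else list(medial = model, lateral = model)
  stopifnot(inherits(models$medial, "condyle_model"),
            inherits(models$lateral, "condyle_model"))
  px <- img$pixels
  if (is.null(joint_row)) joint_row <- round(roi$center_px["row"])
  s <- img$spacing_mm
  lo <- stats::quantile(px, 0.2); hi <- stats::quantile(px, 0.98)
  thr <- (lo + hi) / 2
  # x of the condylar mass from the distal condyle caps (below any shaft)
  cap_rows <- max(roi$rows[1], joint_row - round(20 / s)):max(1L, joint_row - 1L)
  cap <- px[cap_rows, roi$cols[1]:roi$cols[2], drop = FALSE]
  w <- pmax(cap - thr, 0)
  x_mass <- if (sum(w) > 0) {
    cols <- roi$cols[1]:roi$cols[2]
    img$origin_mm[1] + (sum(t(w) * (cols - 1)) / sum(w)) * s
  } else {
    img$origin_mm[1] + (mean(roi$cols) - 1) * s
  }
  y_joint <- img$origin_mm[2] + (joint_row - 1) * s
  off <- params$condyle_offset_prior
  radii <- params$condyle_radius_prior
  gap <- params$joint_gap_prior
  fits <- list()
  sides <- c("medial", "lateral")
  for (i in 1:2) {
    sgn <- if (i == 1L) -1 else 1                # medial = -offset/2
    ctr <- c(x_mass + sgn * off[1] / 2,
             y_joint - gap / 2 - radii[i] + sgn * off[2] / 2)
    mdl <- models[[sides[i]]]
    fits[[i]] <- fit_condyle_asm(img, mdl, center_init = ctr,
                                 scale_init = radii[i] * sqrt(mdl$k),
                                 params = params)
  }
  names(fits) <- sides
  fits
}

# ---------------------------------------------------------------------------
# Synthetic training set for the shape model

#' Generate a synthetic condyle training set
#'
#' Renders `n` phantoms with jittered condyle geometry (radii, eccentricity,
#' centre offset), extracts the ground-truth contours at fixed angular
#' landmark parameters, and samples appearance profiles from the rendered,
#' preprocessed images — the raw material for [train_condyle_model()].
#'
#' @param n number of phantoms (each contributes 2 contours).
#' @param seed RNG seed.
#' @param params a [run_config()] (preprocessing must match the pipeline's).
#' @param k landmarks per contour.
#' @param profile_len appearance profile length (odd).
#' @return list with elements `medial` and `lateral`, each holding
#'   `contours` and `profiles` suitable for [train_condyle_model()].
#'   Appearance is kept per side because each condyle's landmarks see a
#'   side-specific intensity context (the other condyle's rim, the shaft),
#'   which is what lets the fit lock onto its own rim where the two run
#'   close together.
#' @export
synthetic_condyle_training <- function(n = 8L, seed = 42L,
                                       params = run_config(), k = 32L,
                                       profile_len = 11L) {
  draws <- with_seed(seed, list(
    med = stats::rnorm(n, 19, 1.2), lat = stats::rnorm(n, 22, 1.2),
    ecc = matrix(stats::rnorm(2 * n, 0.97, 0.03), ncol = 2),
    offx = stats::rnorm(n, 4.2, 0.8), offy = stats::rnorm(n, 1.7, 0.5)))
  out <- list(medial = list(contours = list(), profiles = list()),
              lateral = list(contours = list(), profiles = list()))
  for (i in seq_len(n)) {
    spec <- phantom_spec(
      condyle_radii_mm = c(draws$med[i], draws$lat[i]),
      condyle_eccentricity = pmin(pmax(draws$ecc[i, ], 0.88), 1.06),
      condyle_center_offset_mm = c(draws$offx[i], draws$offy[i]),
      seed = seed + i)
    pair <- render_phantom_pair(spec)
    wrk <- preprocess(pair$pre, params$downsample_factor, params$sigma_px)
    for (side in c("medial", "lateral")) {
      ct32 <- pair$truth$condyle_contours[[side]]
      if (nrow(ct32) != k) {                     # resample to k landmarks
        th <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
        ctr <- colMeans(ct32)
        ct32 <- t(vapply(th, function(a) {
          hits <- line_polygon_intersections(ctr, c(cos(a), sin(a)), ct32)
          d <- (hits[, 1] - ctr[1]) * cos(a) + (hits[, 2] - ctr[2]) * sin(a)
          hits[which.max(d), ]
        }, numeric(2)))
      }
      out[[side]]$contours[[i]] <- ct32
      out[[side]]$profiles[[i]] <- sample_profiles(
        wrk, ct32, contour_normals(ct32), profile_len, wrk$spacing_mm)
    }
  }
  out
}

# Cached default model (package-local environment, keyed by seed)
.sk_env <- new.env(parent = emptyenv())

#' Default condyle model pair trained on synthetic phantoms
#'
#' Trains (once per session and seed) a medial and a lateral condyle
#' shape/appearance model from [synthetic_condyle_training()] and caches
#' the pair.
#'
#' @param seed training seed.
#' @param params a [run_config()].
#' @return A `condyle_model_pair`: list with `medial` and `lateral`
#'   [train_condyle_model()] objects.
#' @export
default_condyle_model <- function(seed = 42L, params = run_config()) {
  key <- sprintf("model_%d_%d_%g", seed, params$downsample_factor,
                 params$sigma_px)
  if (!is.null(.sk_env[[key]])) return(.sk_env[[key]])
  tr <- synthetic_condyle_training(seed = seed, params = params)
  m <- structure(list(
    medial = train_condyle_model(tr$medial$contours, tr$medial$profiles,
                                 var_keep = params$asm_var_keep),
    lateral = train_condyle_model(tr$lateral$contours, tr$lateral$profiles,
                                  var_keep = params$asm_var_keep)),
    class = "condyle_model_pair")
  .sk_env[[key]] <- m
  m
}

#' @export
print.condyle_model_pair <- function(x, ...) {
  cat("<condyle_model_pair>\n  medial:  "); print(x$medial)
  cat("  lateral: "); print(x$lateral)
  invisible(x)
}

# mean condyle area of a model or model pair, for QC
model_mean_area <- function(model) {
  if (inherits(model, "condyle_model_pair"))
    mean(c(model$medial$mean_area_mm2, model$lateral$mean_area_mm2))
  else model$mean_area_mm2
}
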