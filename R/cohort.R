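# Simulated measurement cohorts with the statistical structure of the
# reference population: group-specific normal translation distributions per
# method, normal covariates, and an optional logistic accuracy link for
# factor-analysis recovery experiments.

#' Parameters of a simulated measurement cohort
#'
#' Defaults reproduce the reference population: 177 patients, 72.9%
#' complete-tear prevalence, per-method translation means/SDs of
#' 10.50+/-5.27, 10.58+/-4.83, 8.85+/-5.02, 9.78+/-4.89 mm in the torn
#' group versus 6.49+/-3.46, 6.77+/-3.17, 5.07+/-2.80, 5.82+/-2.93 mm
#' intact, and covariate distributions with mean/SD: age 28.4/10.5 y,
#' interval 20.44/13.80 d, flexion 38.47/11.22 deg, intercondylar
#' 4.53/3.61 mm, force-joint distance 39.70/11.74 mm, force-joint angle
#' -10.58/9.30 deg, 81.4% male.
#'
#' @param n_total number of patients.
#' @param prevalence fraction with a complete tear, in `[0, 1]`.
#' @param translation_torn,translation_intact `4 x 2` matrices
#'   (rows = methods, cols = mean, sd) of translation in mm.
#' @param covariate_mean_sd named list of `c(mean, sd)` for the continuous
#'   covariates `age`, `interval_d`, `flexion_deg`, `intercondylar_mm`,
#'   `fj_dist_mm`, `fj_angle_deg`.
#' @param male_fraction probability of male gender.
#' @param accuracy_link_betas optional named vector of logistic slopes (any
#'   of the covariate names plus `male`) generating a per-patient
#'   correct/incorrect indicator; an optional `intercept` element sets the
#'   baseline, otherwise it is chosen so the mean accuracy is ~0.729 at the
#'   covariate means.
#' @param seed RNG seed.
#' @return Object of class `cohort_params`.
#' @export
cohort_params <- function(
    n_total = 177L,
    prevalence = 129 / 177,
    translation_torn = rbind(c(10.50, 5.27), c(10.58, 4.83),
                             c(8.85, 5.02), c(9.78, 4.89)),
    translation_intact = rbind(c(6.49, 3.46), c(6.77, 3.17),
                               c(5.07, 2.80), c(5.82, 2.93)),
    covariate_mean_sd = list(
      age = c(28.4, 10.5), interval_d = c(20.44, 13.80),
      flexion_deg = c(38.47, 11.22), intercondylar_mm = c(4.53, 3.61),
      fj_dist_mm = c(39.70, 11.74), fj_angle_deg = c(-10.58, 9.30)),
    male_fraction = 144 / 177,
    accuracy_link_betas = NULL,
    seed = 1L) {
  if (n_total < 0) stop("'n_total' must be >= 0")
  if (prevalence < 0 || prevalence > 1)
    stop("'prevalence' must be in [0, 1]")
  tt <- as.matrix(translation_torn); ti <- as.matrix(translation_intact)
  if (!all(dim(tt) == c(4, 2)) || !all(dim(ti) == c(4, 2)))
    stop("translation parameter matrices must be 4 x 2 (method x mean/sd)")
  if (any(tt[, 2] < 0) || any(ti[, 2] < 0) ||
      any(vapply(covariate_mean_sd, function(v) v[2] < 0, logical(1))))
    stop("all SDs must be >= 0")
  structure(list(n_total = as.integer(n_total), prevalence = prevalence,
                 translation_torn = tt, translation_intact = ti,
                 covariate_mean_sd = covariate_mean_sd,
                 male_fraction = male_fraction,
                 accuracy_link_betas = accuracy_link_betas,
                 seed = as.integer(seed)), class = "cohort_params")
}

#' Simulate a measurement cohort
#'
#' Draws tear status, per-method translations from the group-specific
#' normals, covariates from their normals (gender Bernoulli) and, when an
#' accuracy link is given, a per-patient correct/incorrect indicator from
#' the logistic model. Reproducible by the seed in `params`.
#'
#' @param params a [cohort_params()].
#' @return data.frame with columns `id`, `acl_torn`, `m1`..`m4`
#'   (translation, mm), `age`, `male`, `interval_d`, `flexion_deg`,
#'   `intercondylar_mm`, `fj_dist_mm`, `fj_angle_deg` and, with an accuracy
#'   link, `correct`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_total
  cm <- params$covariate_mean_sd
  empty <- data.frame(id = integer(0), acl_torn = integer(0),
                      m1 = numeric(0), m2 = numeric(0), m3 = numeric(0),
                      m4 = numeric(0), age = numeric(0), male = integer(0),
                      interval_d = numeric(0), flexion_deg = numeric(0),
                      intercondylar_mm = numeric(0), fj_dist_mm = numeric(0),
                      fj_angle_deg = numeric(0))
  if (n == 0L) return(empty)
  with_seed(params$seed, {
    torn <- stats::rbinom(n, 1L, params$prevalence)
    tr <- sapply(1:4, function(m) {
      mu <- ifelse(torn == 1L, params$translation_torn[m, 1],
                   params$translation_intact[m, 1])
      sd <- ifelse(torn == 1L, params$translation_torn[m, 2],
                   params$translation_intact[m, 2])
      stats::rnorm(n, mu, sd)
    })
    d <- data.frame(
      id = seq_len(n), acl_torn = torn,
      m1 = tr[, 1], m2 = tr[, 2], m3 = tr[, 3], m4 = tr[, 4],
      age = stats::rnorm(n, cm$age[1], cm$age[2]),
      male = stats::rbinom(n, 1L, params$male_fraction),
      interval_d = stats::rnorm(n, cm$interval_d[1], cm$interval_d[2]),
      flexion_deg = stats::rnorm(n, cm$flexion_deg[1], cm$flexion_deg[2]),
      intercondylar_mm = stats::rnorm(n, cm$intercondylar_mm[1],
                                      cm$intercondylar_mm[2]),
      fj_dist_mm = stats::rnorm(n, cm$fj_dist_mm[1], cm$fj_dist_mm[2]),
      fj_angle_deg = stats::rnorm(n, cm$fj_angle_deg[1], cm$fj_angle_deg[2]))
    bet <- params$accuracy_link_betas
    if (!is.null(bet)) {
      covs <- c(names(cm), "male")
      means <- c(vapply(cm, `[`, numeric(1), 1), male = params$male_fraction)
      eta <- rep(0, n)
      for (v in intersect(names(bet), covs)) eta <- eta + bet[[v]] * d[[v]]
      b0 <- if ("intercept" %in% names(bet)) bet[["intercept"]] else {
        stats::qlogis(0.729) -
          sum(vapply(intersect(names(bet), covs),
                     function(v) bet[[v]] * means[[v]], numeric(1)))
      }
      d$correct <- stats::rbinom(n, 1L, stats::plogis(b0 + eta))
    }
    d
  })
}

#' Write / read a cohort table as CSV
#'
#' @param cohort data.frame from [generate_cohort()] (or the same schema).
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("cohort file not found: %s", path))
  d <- utils::read.csv(path)
  need <- c("acl_torn", "m1", "m2", "m3", "m4")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(sprintf("cohort CSV is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  d
}
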