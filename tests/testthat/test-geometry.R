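# The four tibial-position constructions, translation, and the technical
# factors, checked against analytic circle-condyle oracles.

test_that("tangent line to a circle matches the analytic offsets", {
  circ <- make_circle_seg(rbind(c(0, 0), c(0, 0)), c(20, 20),
                          c(0, -50), c(0, -1), c(0, 50))$condyle_contours[[1]]
  tg <- tangent_line(circ, c(0, 1), "posterior")
  # polygon support of a k-gon inscribed in the circle: max vertex error
  k <- nrow(circ)
  expect_equal(tg$offset, -20, tolerance = 20 * (1 - cos(pi / k)) + 1e-9)
  tga <- tangent_line(circ, c(0, 1), "anterior")
  expect_equal(tga$offset, 20, tolerance = 20 * (1 - cos(pi / k)) + 1e-9)
  # equivariance under translation
  t <- c(13.2, -4.7)
  tg2 <- tangent_line(sweep(circ, 2, t, `+`), c(0, 1), "posterior")
  expect_equal(tg2$point, tg$point + t)
  expect_equal(tg2$offset, tg$offset + t[1])
})

test_that("tangent ties break to the smaller row and degeneracy errors", {
  sq <- rbind(c(0, 0), c(0, 10), c(10, 10), c(10, 0))
  tg <- tangent_line(sq, c(0, 1), "posterior")   # left side is tangent
  expect_equal(tg$point, c(0, 0))                # smaller y among (0,0),(0,10)
  seg3 <- rbind(c(0, 0), c(0, 5), c(0, 9))
  expect_error(tangent_line(seg3, c(0, 1), "posterior"), "degenerate")
})

test_that("method constructions reproduce forced symmetric cases", {
  # m4: centres (10,0) and (14,0); vertical tibial axis through x = 12 -> 0
  seg <- make_circle_seg(rbind(c(10, 0), c(14, 0)), c(3, 3),
                         fem_point = c(12, -40), fem_dir = c(0, -1),
                         tib_point = c(12, 40))
  expect_equal(tibial_position_m4(seg)$tibial_position_mm, 0)
  seg$tibial_axis <- axis_line(c(17, 40), c(0, 1), "tibial")
  expect_equal(tibial_position_m4(seg)$tibial_position_mm, 5)
  # symmetric circles about a vertical femoral axis: m1/m4 reference on axis
  seg2 <- make_circle_seg(rbind(c(95, 100), c(105, 100)), c(20, 20),
                          fem_point = c(100, 50), fem_dir = c(0, -1),
                          tib_point = c(100, 160))
  expect_equal(tibial_position_m1(seg2)$tibial_position_mm, 0, tolerance = 1e-9)
  expect_equal(tibial_position_m4(seg2)$tibial_position_mm, 0, tolerance = 1e-9)
  # posterior tangents symmetric about the tibial axis: m2 midline on axis
  seg3 <- make_circle_seg(rbind(c(110, 100), c(130, 100)), c(20, 20),
                          fem_point = c(120, 50), fem_dir = c(0, -1),
                          tib_point = c(100, 160))
  k <- nrow(seg3$condyle_contours$medial)
  tol_poly <- 20 * (1 - cos(pi / k)) + 1e-9
  expect_equal(tibial_position_m2(seg3)$tibial_position_mm, 0,
               tolerance = tol_poly)
  expect_equal(tibial_position_m3(seg3)$tibial_position_mm, 0,
               tolerance = tol_poly)
  # a 5 mm anterior shift of the tibial axis adds exactly 5 mm in every method
  shift_axis <- function(seg, dx) {
    seg$tibial_axis <- axis_line(seg$tibial_axis$point + c(dx, 0),
                                 c(0, 1), "tibial")
    seg
  }
  for (f in list(tibial_position_m1, tibial_position_m2,
                 tibial_position_m3, tibial_position_m4))
    expect_equal(f(shift_axis(seg2, 5))$tibial_position_mm -
                   f(seg2)$tibial_position_mm, 5, tolerance = 1e-9)
})

test_that("each method matches its vertex-level analytic construction", {
  set.seed(31)
  for (i in 1:8) {
    cm <- c(runif(1, 90, 100), runif(1, 95, 105))
    cl <- cm + c(runif(1, 2, 6), runif(1, -2, 2))
    radii <- runif(2, 15, 25)
    xt <- runif(1, 95, 110)
    seg <- make_circle_seg(rbind(cm, cl), radii,
                           fem_point = c(cm[1] + 2, 40),
                           fem_dir = c(0, -1),
                           tib_point = c(xt, 160), k = 64L)
    med <- seg$condyle_contours$medial; lat <- seg$condyle_contours$lateral
    # m2 oracle: vertical tangents = min x over vertices; midline offset
    o2 <- (min(med[, 1]) + min(lat[, 1])) / 2
    expect_equal(tibial_position_m2(seg)$tibial_position_mm, xt - o2,
                 tolerance = 1e-6)
    # m3 oracle: tangent points = argmin x vertices (vertical femoral axis)
    p3 <- (med[which.min(med[, 1]), ] + lat[which.min(lat[, 1]), ]) / 2
    expect_equal(tibial_position_m3(seg)$tibial_position_mm, xt - p3[1],
                 tolerance = 1e-6)
    # m4 oracle: centroid midpoint
    p4 <- (colMeans(med) + colMeans(lat)) / 2
    expect_equal(tibial_position_m4(seg)$tibial_position_mm, xt - p4[1],
                 tolerance = 1e-6)
    # m1 oracle: distal-most crossing of the vertical line x = fem x with
    # each polygon, found by explicit segment scanning
    xf <- cm[1] + 2
    crossings <- function(poly) {
      k <- nrow(poly); ys <- c()
      for (a in seq_len(k)) {
        b <- if (a == k) 1L else a + 1L
        x1 <- poly[a, 1]; x2 <- poly[b, 1]
        if ((x1 - xf) * (x2 - xf) <= 0 && x1 != x2) {
          t <- (xf - x1) / (x2 - x1)
          ys <- c(ys, poly[a, 2] + t * (poly[b, 2] - poly[a, 2]))
        }
      }
      ys
    }
    y1 <- max(crossings(med)); y2 <- max(crossings(lat))
    if (length(y1) && length(y2)) {
      ref1 <- c(xf, (y1 + y2) / 2)
      expect_equal(tibial_position_m1(seg)$tibial_position_mm, xt - ref1[1],
                   tolerance = 1e-6)
    }
  }
})

test_that("translation is zero on identical views and antisymmetric", {
  seg <- make_circle_seg(rbind(c(95, 100), c(105, 100)), c(20, 18),
                         fem_point = c(100, 50), fem_dir = c(0, -1),
                         tib_point = c(102, 160))
  seg$qc <- c(m1 = TRUE, m2 = TRUE, m3 = TRUE, m4 = TRUE)
  seg2 <- seg
  seg2$tibial_axis <- axis_line(c(109, 160), c(0, 1), "tibial")
  for (m in 1:4) {
    expect_equal(tibial_translation(seg, seg, m)$translation_mm, 0)
    fwd <- tibial_translation(seg, seg2, m)
    bwd <- tibial_translation(seg2, seg, m)
    expect_equal(fwd$translation_mm, 7, tolerance = 1e-9)
    expect_equal(bwd$translation_mm, -fwd$translation_mm)
    expect_equal(tibial_translation(seg, seg2, m, absolute = TRUE)$translation_mm,
                 abs(fwd$translation_mm))
  }
  # failed qc makes the translation unavailable for that method only
  seg_fail <- seg; seg_fail$qc["m2"] <- FALSE
  expect_false(tibial_translation(seg_fail, seg2, 2)$success)
  expect_true(tibial_translation(seg_fail, seg2, 1)$success)
})

test_that("flexion angle follows the clinical convention", {
  seg <- list(femoral_axis = axis_line(c(0, 0), c(0, -1), "femoral"),
              tibial_axis = axis_line(c(0, 0), c(0, 1), "tibial"))
  expect_equal(flexion_angle(seg), 0)            # straight leg
  a <- 40 * pi / 180
  seg$tibial_axis <- axis_line(c(0, 0), c(sin(a), cos(a)), "tibial")
  expect_equal(flexion_angle(seg), 40, tolerance = 1e-9)
  expect_error(flexion_angle(list(femoral_axis = NULL,
                                  tibial_axis = seg$tibial_axis)), "axes")
})

test_that("intercondylar distance equals the centroid distance", {
  seg <- make_circle_seg(rbind(c(10, 0), c(13, 4)), c(3, 3),
                         fem_point = c(0, 0), fem_dir = c(0, -1),
                         tib_point = c(0, 10))
  expect_equal(intercondylar_distance(seg), 5)   # 3-4-5 triangle
  seg$condyle_centers <- rbind(c(7, 7), c(7, 7))
  expect_equal(intercondylar_distance(seg), 0)
  seg$converged <- c(medial = TRUE, lateral = FALSE)
  expect_true(is.na(intercondylar_distance(seg)))
})

test_that("force-joint metrics follow the stated sign conventions", {
  plat_p <- c(100, 200); plat_d <- c(1, 0)
  # skin point on the plateau -> zero distance
  fl0 <- force_line(c(60, 200), c(1, 0))
  m0 <- force_joint_metrics(fl0, plat_p, plat_d)
  expect_equal(m0$distance_mm, 0)
  # 39.70 mm distal, force parallel to the plateau
  fl <- force_line(c(60, 239.70), c(1, 0))
  m <- force_joint_metrics(fl, plat_p, plat_d)
  expect_equal(m$distance_mm, 39.70)
  expect_equal(m$angle_deg, 0)
  # mirrored about the plateau: distance flips sign
  flm <- force_line(c(60, 160.30), c(1, 0))
  expect_equal(force_joint_metrics(flm, plat_p, plat_d)$distance_mm, -39.70)
  # pointing toward the plateau from below -> positive angle; away -> negative
  a <- 10.58 * pi / 180
  toward <- force_joint_metrics(force_line(c(60, 240), c(cos(a), -sin(a))),
                                plat_p, plat_d)
  away <- force_joint_metrics(force_line(c(60, 240), c(cos(a), sin(a))),
                              plat_p, plat_d)
  expect_equal(toward$angle_deg, 10.58, tolerance = 1e-9)
  expect_equal(away$angle_deg, -10.58, tolerance = 1e-9)
})

test_that("measurements are invariant to rigid motions of the scene", {
  base <- make_circle_seg(rbind(c(95, 100), c(103, 102)), c(20, 17),
                          fem_point = c(98, 50), fem_dir = c(-0.2, -0.98),
                          tib_point = c(102, 160), k = 64L)
  vals <- function(seg, distal = c(0, 1)) {
    c(m4 = tibial_position_m4(seg)$tibial_position_mm,
      flex = flexion_angle(seg),
      ic = intercondylar_distance(seg))
  }
  v0 <- vals(base)
  # pure translation: everything identical
  t <- c(31.5, -12.25)
  shifted <- base
  shifted$condyle_contours <- lapply(base$condyle_contours,
                                     function(ct) sweep(ct, 2, t, `+`))
  shifted$condyle_centers <- sweep(base$condyle_centers, 2, t, `+`)
  shifted$femoral_axis <- axis_line(base$femoral_axis$point + t,
                                    base$femoral_axis$direction, "femoral")
  shifted$tibial_axis <- axis_line(base$tibial_axis$point + t,
                                   base$tibial_axis$direction, "tibial")
  expect_equal(vals(shifted), v0, tolerance = 1e-9)
  # rotation: angles and distances unchanged (m4 needs the rotated anterior
  # reference, so compare only the rotation-invariant factors)
  th <- 17 * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  rot_pt <- function(p) as.vector(R %*% p)
  rotated <- base
  rotated$condyle_contours <- lapply(base$condyle_contours,
                                     function(ct) t(R %*% t(ct)))
  rotated$condyle_centers <- t(R %*% t(base$condyle_centers))
  rotated$femoral_axis <- axis_line(rot_pt(base$femoral_axis$point),
                                    rot_pt(base$femoral_axis$direction), "femoral")
  rotated$tibial_axis <- axis_line(rot_pt(base$tibial_axis$point),
                                   rot_pt(base$tibial_axis$direction), "tibial")
  expect_equal(flexion_angle(rotated), v0[["flex"]], tolerance = 1e-9)
  expect_equal(intercondylar_distance(rotated), v0[["ic"]], tolerance = 1e-9)
  fl <- force_line(c(60, 240), c(1, 0))
  f0 <- force_joint_metrics(fl, c(100, 200), c(1, 0))
  fr <- force_joint_metrics(force_line(rot_pt(c(60, 240)), rot_pt(c(1, 0))),
                            rot_pt(c(100, 200)), rot_pt(c(1, 0)),
                            distal = rot_pt(c(0, 1)))
  expect_equal(fr$distance_mm, f0$distance_mm, tolerance = 1e-9)
  expect_equal(fr$angle_deg, f0$angle_deg, tolerance = 1e-9)
})

test_that("central methods are less sensitive to condylar offset than tangent methods", {
  # growing the projectional offset between the condyle centres perturbs the
  # tangent-based method 3 more than the central methods 1 and 4
  pos <- function(off) {
    # move only the lateral condyle, as projection under limb rotation does
    seg <- make_circle_seg(rbind(c(100, 100), c(100 + off, 102)),
                           c(20, 20), fem_point = c(100, 50),
                           fem_dir = c(0, -1), tib_point = c(105, 160),
                           k = 128L)
    c(m1 = tibial_position_m1(seg)$tibial_position_mm,
      m3 = tibial_position_m3(seg)$tibial_position_mm,
      m4 = tibial_position_m4(seg)$tibial_position_mm)
  }
  p0 <- pos(0); p8 <- pos(8)
  dev <- abs(p8 - p0)
  expect_lte(dev[["m1"]], dev[["m3"]] + 1e-9)
  expect_lte(dev[["m4"]], dev[["m3"]] + 1e-9)
})
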