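# Joint localization, edge paths, axis fitting, ROI and QC.

test_that("joint row is the forced minimum of a 3-row band", {
  px <- matrix(9, 9, 5); px[5, ] <- 5
  img <- image2d(px, 1)
  expect_equal(locate_joint_row(img, c(4L, 6L)), 5L)
})

test_that("with two dips the deeper one wins, matching a brute-force scan", {
  set.seed(21)
  for (i in 1:10) {
    px <- matrix(100 + rnorm(60 * 8, sd = 0.1), 60, 8)
    d1 <- sample(15:25, 1); d2 <- sample(35:45, 1)
    px[d1, ] <- px[d1, ] * 0.8
    px[d2, ] <- px[d2, ] * 0.5              # deeper dip
    img <- image2d(px, 1)
    band <- c(10L, 50L)
    got <- locate_joint_row(img, band)
    oracle <- (band[1]:band[2])[which.min(rowSums(px[band[1]:band[2], ]))]
    expect_identical(got, oracle)
    expect_identical(got, d2)
  }
})

test_that("a strictly monotone row-sum profile raises a no-joint error", {
  px <- matrix(rep(1:50, 6), 50, 6)
  expect_error(locate_joint_row(image2d(px, 1), c(10L, 40L)), "monotone")
})

test_that("phantom joint row is found within half the joint gap", {
  p <- sk_pair(shift = 0, noise = 0)
  wrk <- preprocess(p$pre, sk_cfg$downsample_factor, sk_cfg$sigma_px)
  jr <- locate_joint_row(wrk)
  jr_orig <- (jr - 1) * sk_cfg$downsample_factor + 1
  half_gap_px <- phantom_spec()$joint_gap_mm / 2 / p$pre$spacing_mm
  expect_lt(abs(jr_orig - p$truth$joint_row_px), half_gap_px + 1)
})

test_that("DP path equals exhaustive enumeration on small cost grids", {
  set.seed(5)
  for (i in 1:12) {
    nr <- sample(3:6, 1); nc <- sample(3:6, 1)
    cost <- matrix(runif(nr * nc), nr, nc)
    if (i %% 3 == 0) cost[sample(nr * nc, 3)] <- Inf   # forbidden cells
    ms <- sample(1:3, 1); be <- runif(1, 0, 0.5)
    oracle <- enum_min_path_cost(cost, ms, be)
    if (!is.finite(oracle)) next
    got <- edge_path_dp(cost, ms, be)
    expect_equal(got$total_cost, oracle, tolerance = 1e-12)
    # the returned path realizes that cost and respects the step bound
    path_cost <- sum(cost[cbind(seq_len(nr), got$cols)]) +
      be * sum(abs(diff(got$cols)))
    expect_equal(path_cost, oracle, tolerance = 1e-12)
    expect_true(all(abs(diff(got$cols)) <= ms))
  }
})

test_that("edges hug a vertical intensity step and fail on blank images", {
  px <- matrix(0, 60, 40); px[, 20:32] <- 100       # bright vertical band
  img <- image2d(px, 1)
  edges <- segment_bone_edges(img, 5L, "tibia", sk_cfg)
  expect_true(all(abs(edges$posterior$col - 19.5) <= 1))
  expect_true(all(abs(edges$anterior$col - 32.5) <= 1))
  blank <- image2d(matrix(50, 400, 40), 1)
  expect_error(segment_bone_edges(blank, 200L, "femur", sk_cfg), "femur")
})

test_that("noise-free phantom edges track the true shaft boundaries", {
  p <- sk_pair(shift = 0, noise = 0)
  spec <- phantom_spec()
  wrk <- preprocess(p$pre, sk_cfg$downsample_factor, sk_cfg$sigma_px)
  jr <- locate_joint_row(wrk)
  tr <- p$truth
  tib <- segment_bone_edges(wrk, jr, "tibia", sk_cfg)
  x_t <- tr$tibial_axis_pre$point[1]
  for (side in c("anterior", "posterior")) {
    sgn <- if (side == "anterior") 1 else -1
    x_true <- x_t + sgn * spec$tibial_shaft_width_mm / 2
    col_true <- (x_true - wrk$origin_mm[1]) / wrk$spacing_mm + 1
    dev <- abs(tib[[side]]$col - col_true)
    expect_lt(mean(dev), 2)
  }
  fem <- segment_bone_edges(wrk, jr, "femur", sk_cfg)
  fa <- tr$femoral_axis
  phi <- spec$flexion_angle_deg * pi / 180
  half_w <- spec$femoral_shaft_width_mm / 2 / cos(phi)  # horizontal offset
  for (side in c("anterior", "posterior")) {
    sgn <- if (side == "anterior") 1 else -1
    e <- fem[[side]]
    y_mm <- wrk$origin_mm[2] + (e$row - 1) * wrk$spacing_mm
    x_axis <- fa$point[1] + (y_mm - fa$point[2]) * fa$direction[1] / fa$direction[2]
    col_true <- (x_axis + sgn * half_w - wrk$origin_mm[1]) / wrk$spacing_mm + 1
    expect_lt(mean(abs(e$col - col_true)), 2)
  }
  # anterior edge is anterior of the posterior edge at every row
  expect_true(all(tib$anterior$col > tib$posterior$col))
  expect_true(all(fem$anterior$col > fem$posterior$col))
})

test_that("axis fit recovers exact lines and is translation invariant", {
  # parallel vertical edges -> vertical axis at the midline
  rows <- 1:200
  ant <- data.frame(row = rows, col = 140)
  post <- data.frame(row = rows, col = 100)
  ax <- fit_axis(ant, post, 210L, 1, c(80, 140))
  expect_equal(abs(ax$direction[2]), 1)
  expect_equal(ax$point[1], 119)            # col 120 in mm with origin 0
  # slanted midline: TLS oracle via the smallest-eigenvector normal
  set.seed(9)
  for (i in 1:5) {
    slope <- runif(1, -0.4, 0.4); x0 <- runif(1, 80, 120)
    mid <- x0 + slope * (rows - 1)
    ant <- data.frame(row = rows, col = mid + 15)
    post <- data.frame(row = rows, col = mid - 15)
    ax <- fit_axis(ant, post, 210L, 1, c(80, 140))
    band_rows <- rows[abs(rows - 210) >= 80 & abs(rows - 210) <= 140]
    pts <- cbind(mid[band_rows] - 1, band_rows - 1)
    cc <- sweep(pts, 2, colMeans(pts))
    n_or <- eigen(crossprod(cc), symmetric = TRUE)$vectors[, 2]  # normal
    expect_lt(abs(sum(ax$direction * n_or)), 1e-6)
    expect_lt(abs(sum((ax$point - colMeans(pts)) * n_or)), 1e-6)
    # rigid shift of the content shifts the axis point, same direction
    sh <- 7.25
    ax2 <- fit_axis(transform(ant, col = col + sh),
                    transform(post, col = col + sh), 210L, 1, c(80, 140))
    expect_equal(ax2$direction, ax$direction, tolerance = 1e-9)
    expect_equal(ax2$point[1] - ax$point[1], sh, tolerance = 1e-9)
  }
})

test_that("an axis band not fully covered raises an error naming the span", {
  rows <- 140:209                            # only 1-70 mm from the joint
  ant <- data.frame(row = rows, col = 140)
  post <- data.frame(row = rows, col = 100)
  expect_error(fit_axis(ant, post, 210L, 1, c(80, 140)), "cover")
})

test_that("condyle ROI is centred on the axis at the joint row and clipped", {
  img <- image2d(matrix(0, 300, 200), 1)
  ax <- axis_line(c(99, 0), c(0, -1), "femoral")    # vertical at col 100
  roi <- define_condyle_roi(150L, ax, img, 100)
  expect_equal(unname(roi$center_px["col"]), 100)
  expect_equal(unname(roi$center_px["row"]), 150)
  expect_equal(roi$rows, c(100L, 200L))
  roi2 <- define_condyle_roi(30L, ax, img, 100)     # clipped at the top
  expect_equal(roi2$rows[1], 1L)
  expect_error(define_condyle_roi(150L, axis_line(c(900, 0), c(0, 1), "femoral"),
                                  img, 50), "outside")
})

test_that("qc flags partition exactly as component failures dictate", {
  p <- sk_pair(shift = 0, noise = 0)
  seg <- segment_knee(p$pre, sk_cfg, sk_model())
  expect_true(all(seg$qc))
  seg_badfit <- seg; seg_badfit$converged[] <- FALSE
  expect_equal(unname(qc_segmentation(seg_badfit)),
               c(TRUE, TRUE, TRUE, FALSE))
  seg_noaxis <- seg; seg_noaxis$femoral_axis <- NULL
  expect_false(any(qc_segmentation(seg_noaxis)))
  seg_tiny <- seg
  seg_tiny$condyle_contours$medial <- seg$condyle_contours$medial / 10
  expect_false(any(qc_segmentation(seg_tiny)[1:3]))
})
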