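# Independent oracles used across the suite. Each is a deliberately naive
# implementation (enumeration, pair counting, closed forms) kept separate
# from the package's code paths.

# Exhaustive minimal-cost monotone path: expands every admissible column
# sequence row by row without any collapsing, so it is independent of the
# dynamic program it checks. Returns the minimal total cost.
enum_min_path_cost <- function(cost, max_step, beta) {
  nc <- ncol(cost)
  cols <- seq_len(nc)
  cur_col <- cols
  cur_cost <- cost[1, ]
  keep <- is.finite(cur_cost)
  cur_col <- cur_col[keep]; cur_cost <- cur_cost[keep]
  for (r in seq_len(nrow(cost))[-1]) {
    new_col <- integer(0); new_cost <- numeric(0)
    for (dc in seq(-max_step, max_step)) {
      nxt <- cur_col + dc
      ok <- nxt >= 1L & nxt <= nc
      cc <- cur_cost[ok] + beta * abs(dc) + cost[r, nxt[ok]]
      fin <- is.finite(cc)
      new_col <- c(new_col, nxt[ok][fin])
      new_cost <- c(new_cost, cc[fin])
    }
    cur_col <- new_col; cur_cost <- new_cost
    if (!length(cur_cost)) return(Inf)
  }
  min(cur_cost)
}

# Mann-Whitney AUC by direct pair counting (ties count one half).
auc_pair_count <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  comp <- outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`)
  mean(comp)
}

# Youden cutoff by brute-force threshold scan.
youden_scan <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- sort(unique(scores))
  j <- vapply(thr, function(t)
    mean(scores[labels] >= t) + mean(scores[!labels] < t) - 1, numeric(1))
  best <- max(j)
  thr[which(j >= best - 1e-12)][1]        # lowest threshold among ties
}

# Two-sided Fisher p by full hypergeometric enumeration.
fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  av <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, av) * choose(r2, c1 - av) / choose(n, c1)
  p_obs <- pr[av == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Build a segmentation-like object from analytic circle-condyle geometry,
# for the geometry-module oracles (landmarks ON the circles).
make_circle_seg <- function(centers, radii, fem_point, fem_dir,
                            tib_point, tib_dir = c(0, 1), k = 64L,
                            anterior = "+col") {
  circ <- function(ctr, r) {
    th <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
    cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th))
  }
  list(femoral_axis = axis_line(fem_point, fem_dir, "femoral"),
       tibial_axis = axis_line(tib_point, tib_dir, "tibial"),
       condyle_contours = list(medial = circ(centers[1, ], radii[1]),
                               lateral = circ(centers[2, ], radii[2])),
       condyle_centers = centers,
       converged = c(medial = TRUE, lateral = TRUE),
       anterior = anterior)
}
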