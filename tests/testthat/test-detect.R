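# Detection algorithm: delineation, amplitude operators, ROC optimization,
# classification, metrics.

# toy EGM grid: depolarization spike at t_dep, one repolarization bump per
# electrode at a chosen time and amplitude
toy_egm <- function(bump_t, bump_a, t_max = 500, t_dep = 20) {
  t <- seq(0, t_max)
  nE <- length(bump_t)
  phi <- vapply(seq_len(nE), function(e) {
    x <- 5 * exp(-((t - t_dep) / 3)^2) - 5 * exp(-((t - t_dep - 4) / 3)^2)
    x + bump_a[e] * exp(-((t - bump_t[e]) / 12)^2)
  }, numeric(length(t)))
  n <- ceiling(sqrt(nE))
  grid <- tidyr::expand_grid(row = seq_len(n), col = seq_len(n))[seq_len(nE), ]
  structure(list(phi = phi, t = t, grid = grid, n_rows = n, n_cols = n,
                 sample_dt = 1, z_mm = 1, normalized = TRUE,
                 filter = "none", noise = "none"),
            class = "achmap_egm")
}

test_that("delineation applies the stated window rule", {
  egm <- toy_egm(bump_t = c(220, 260, 240, 250), bump_a = c(1, 0.4, 0.6, 0.5))
  w <- delineate(egm)
  expect_equal(w$t_R, 220)             # largest |peak| among electrodes
  expect_equal(w$tw_on, 190)
  expect_equal(w$tw_off, 370)
  # the reference time sits on the depolarization downslope
  expect_lt(abs(w$t_ref - 22), 5)
  expect_gte(w$tw_on, w$t_ref + 70)    # t_R searched >= 100 ms after t_ref
  # translation equivariance: shifting all signals shifts every landmark
  egm2 <- toy_egm(bump_t = c(270, 310, 290, 300), bump_a = c(1, 0.4, 0.6, 0.5),
                  t_dep = 70)
  w2 <- delineate(egm2)
  expect_equal(w2$t_ref - w$t_ref, 50, tolerance = 1e-9)
  expect_equal(w2$t_R - w$t_R, 50)
  expect_equal(w2$tw_on - w$tw_on, 50)
})

test_that("delineation errors when no repolarization wave exists", {
  egm <- toy_egm(bump_t = c(220, 240), bump_a = c(0, 0))
  expect_error(delineate(egm), "no repolarization peak")
})

test_that("repolarization amplitude follows the largest-|extremum| rule", {
  t <- 0:400
  w <- list(tw_on = 100, tw_off = 300)
  mk <- function(a1, a2) a1 * exp(-((t - 180) / 15)^2) +
    a2 * exp(-((t - 250) / 15)^2)
  expect_equal(as.numeric(repol_amplitude(mk(0.5, -0.2), t, w)), 0.5,
               tolerance = 1e-6)
  expect_equal(as.numeric(repol_amplitude(mk(0.5, -0.6), t, w)), -0.6,
               tolerance = 1e-6)
  # exact tie resolves to the positive value and is flagged
  x <- c(rep(0, 50), 0.5, rep(0, 20), -0.5, rep(0, 50))
  tie <- repol_amplitude(x, seq_along(x) + 99, w)
  expect_equal(as.numeric(tie), 0.5)
  expect_true(attr(tie, "tie"))
  expect_error(repol_amplitude(mk(1, 1), t, list(tw_on = 600, tw_off = 700)),
               "empty")
})

test_that("amplitude operators match brute-force scans on random signals", {
  set.seed(42)
  w <- list(tw_on = 0, tw_off = 1e9)
  for (k in 1:1000) {
    n <- sample(20:60, 1)
    x <- round(cumsum(rnorm(n)), 2)   # rounding creates plateaus and ties
    got <- as.numeric(repol_amplitude(x, seq_len(n), w))
    ref <- brute_repol(x)
    expect_identical(abs(got), abs(ref))
    # peak-to-peak operator against direct max - min
    expect_identical(depol_amplitude(x, seq_len(n), c(1, n)),
                     max(x) - min(x))
  }
})

test_that("depolarization amplitude is offset-invariant and zero on flat", {
  t <- 1:100
  x <- sin(t / 8)
  expect_equal(depol_amplitude(x, t, c(1, 100)),
               depol_amplitude(x + 7.3, t, c(1, 100)))
  expect_equal(depol_amplitude(rep(2, 100), t, c(1, 100)), 0)
  expect_equal(depol_amplitude(c(3, -4, 1), 1:3, c(1, 3)), 7)
  expect_error(depol_amplitude(x, t, c(200, 300)), "empty")
})

test_that("ROC optimizer finds the corner-nearest threshold", {
  scores <- c(rnorm(50, 0), rnorm(50, 10))
  truth <- rep(c(FALSE, TRUE), each = 50)
  opt <- roc_optimal_threshold(scores, truth, seq(-5, 15, by = 0.1))
  expect_equal(opt$se, 1)
  expect_equal(opt$sp, 1)
  expect_equal(opt$dist, 0)
  expect_error(roc_optimal_threshold(scores, rep(TRUE, 100), 0:10),
               "both classes")
})

test_that("ROC optimizer matches the exhaustive midpoint oracle", {
  set.seed(7)
  for (k in 1:100) {
    n <- sample(20:80, 1)
    scores <- rnorm(n, mean = ifelse(runif(n) < 0.4, 1, 0))
    truth <- runif(n) < 0.4
    if (!any(truth) || all(truth)) next
    ref <- brute_roc_best(scores, truth)
    # scanning the same midpoints must reproduce the oracle exactly
    s <- sort(unique(scores))
    mids <- c(s[1] - 1, (head(s, -1) + tail(s, -1)) / 2, s[length(s)] + 1)
    opt <- roc_optimal_threshold(scores, truth, mids)
    expect_equal(opt$dist, ref$dist, tolerance = 1e-12)
    # the optimum dominates every grid threshold scanned
    expect_true(all(opt$dist <= opt$roc$dist + 1e-12))
  }
})

test_that("ROC of label-permuted scores hugs the chance diagonal", {
  set.seed(8)
  scores <- rnorm(400)
  truth <- sample(rep(c(TRUE, FALSE), 200))
  opt <- roc_optimal_threshold(scores, truth, quantile(scores, seq(0, 1, 0.02)))
  expect_gt(opt$dist, 0.45)   # best achievable near sqrt(2)/2 for chance
  expect_lt(abs(opt$se - opt$sp), 0.35)
})

test_that("ROC curve agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  scores <- c(rnorm(60, 0, 1.2), rnorm(40, 1.5, 1.2))
  truth <- rep(c(FALSE, TRUE), c(60, 40))
  thr <- sort(unique(scores)) - 1e-9
  ours <- roc_optimal_threshold(scores, truth, thr)
  ref <- pROC::roc(truth, scores, quiet = TRUE, direction = "<")
  # compare (se, sp) at the exact same cutoffs
  co <- pROC::coords(ref, x = thr, input = "threshold",
                     ret = c("sensitivity", "specificity"))
  expect_equal(ours$roc$se, co$sensitivity, tolerance = 1e-9)
  expect_equal(ours$roc$sp, co$specificity, tolerance = 1e-9)
})

test_that("threshold grids follow the stated construction", {
  d_a <- c(2, 4, 6)
  g <- d_threshold_grid(d_a)
  expect_length(g, 40)
  expect_equal(diff(g), rep(0.1, 39))
  expect_equal(g[21], mean(d_a))       # centered at the global mean
  r <- r_threshold_grid(2)
  expect_length(r, 161)                # -80% .. +80% in 1% steps
  expect_equal(r[1], -0.8 * 2)
  expect_equal(r[161], 0.8 * 2)
})

test_that("classification separates regions and honors negative thresholds", {
  amps <- tibble::tibble(row = rep(1:4, each = 4), col = rep(1:4, 4),
                         R_A = c(rep(1, 4), rep(0.1, 8), rep(0.05, 4)),
                         D_A = c(rep(5, 12), rep(1, 4)))
  one <- classify_electrodes(amps, r_th = 0.5, mode = "one_stage")
  expect_equal(sum(one$pred_ach), 4)
  expect_true(all(one$label[1:4] == "ACh"))
  two <- classify_electrodes(amps, r_th = 0.5, d_th = 2, r_th_fibro = -0.1,
                             mode = "two_stage")
  expect_equal(sum(two$pred_fibro), 4)
  # small positive peaks inside fibrotic areas classify as ACh when the
  # fibrotic threshold is negative
  expect_true(all(two$label[13:16] == "ACh+fibro"))
  expect_error(classify_electrodes(amps, r_th = 0.5, mode = "two_stage"),
               "d_th")
})

test_that("classification monotonicity: raising the threshold never raises Se or FPR", {
  set.seed(13)
  amps <- tibble::tibble(row = 1, col = 1:200, R_A = rnorm(200),
                         D_A = runif(200, 2, 8))
  truth <- amps$R_A + rnorm(200, sd = 0.5) > 0.3
  prev_se <- 1; prev_fpr <- 1
  for (th in seq(-2, 2, by = 0.25)) {
    cls <- classify_electrodes(amps, r_th = th, mode = "one_stage")
    m <- detection_metrics(cls$pred_ach, truth)
    expect_lte(m$se, prev_se + 1e-12)
    expect_lte(m$fpr, prev_fpr + 1e-12)
    prev_se <- m$se; prev_fpr <- m$fpr
  }
})

test_that("ground truth uses the center-in-circle rule, boundary inclusive", {
  # dx = 1/16 cm keeps every coordinate exactly representable
  tis <- tissue_model(nx = 41, ny = 41, dx = 0.0625)
  tis$registry <- tibble::tibble(kind = "ACh", x = 1.25, y = 1.25, r = 0.25,
                                 dose = 0.1)
  g <- electrode_grid(tis, n_rows = 5, n_cols = 5, pitch_mm = 2.5, z_mm = 1)
  tr <- ground_truth(g, tis)
  expect_true(tr$truth_ach[g$x == 1.25 & g$y == 1.25])
  expect_false(any(tr$truth_fibro))
  far <- tr$truth_ach[abs(g$x - 1.25) > 0.3 | abs(g$y - 1.25) > 0.3]
  expect_true(all(!far))
  # electrode exactly on the rim counts as inside
  expect_true(all(tr$truth_ach[abs(g$x - 1.25) == 0.25 & g$y == 1.25]))
})

test_that("metrics reproduce hand-computed confusion matrices", {
  expect_equal(detection_metrics(c(TRUE, FALSE), c(TRUE, FALSE)),
               list(ac = 1, se = 1, fpr = 0))
  pred <- c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 3), rep(FALSE, 243))
  truth <- c(rep(TRUE, 10), rep(FALSE, 246))
  m <- detection_metrics(pred, truth)
  expect_equal(m$ac, 251 / 256)
  expect_equal(m$se, 0.8)
  expect_equal(m$fpr, 3 / 246)
  m2 <- detection_metrics(rep(FALSE, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(m2$se, 0)
  expect_equal(m2$fpr, 0)
  expect_error(detection_metrics(logical(0), logical(0)), "empty")
  expect_error(detection_metrics(TRUE, c(TRUE, FALSE)), "mismatch")
})
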