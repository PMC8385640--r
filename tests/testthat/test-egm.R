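# Electrogram forward model: kernel correctness, footprints, normalization,
# filtering, noise injection.

test_that("spatially uniform Vm produces a zero electrogram", {
  f <- random_field(20, 20, nt = 5)
  f$vm <- matrix(rep(seq(-80, 20, length.out = 5), 400), 5, 400)
  phi <- compute_pegm(f, c(0.4, 0.4, 0.1))
  expect_lt(max(abs(phi)), 1e-10)
})

test_that("optimized forward computation matches the naive double loop", {
  for (s in 1:5) {
    f <- random_field(30, 30, nt = 6, seed = s)
    r_prime <- c(runif(1, 0.2, 1), runif(1, 0.2, 1), runif(1, 0.05, 0.2))
    expect_equal(compute_pegm(f, r_prime), brute_pegm(f, r_prime),
                 tolerance = 1e-10)
  }
})

test_that("kernel decays with electrode height on a step gradient", {
  f <- random_field(30, 30, nt = 1)
  step <- matrix(0, 30, 30); step[, 16:30] <- 100   # half tissue at 100 mV
  f$vm <- matrix(as.numeric(t(step)), 1, 900)
  mid <- c(0.58, 0.58)
  amps <- vapply(c(0.05, 0.1, 0.2, 0.4), function(z)
    abs(compute_pegm(f, c(mid, z))), numeric(1))
  expect_true(all(diff(amps) < 0))
})

test_that("EGM is linear in the transmembrane potential field", {
  fa <- random_field(25, 25, nt = 4, seed = 21)
  fb <- random_field(25, 25, nt = 4, seed = 22)
  fsum <- fa; fsum$vm <- fa$vm + fb$vm
  r_prime <- c(0.5, 0.4, 0.1)
  expect_equal(compute_pegm(fsum, r_prime),
               compute_pegm(fa, r_prime) + compute_pegm(fb, r_prime),
               tolerance = 1e-10)
})

test_that("mirror-symmetric wavefronts give mirror-invariant electrograms", {
  spec <- phantom_spec(nx = 41, ny = 41, dx = 0.04, t_total = 300)
  f <- phantom_vm(spec)   # planar wave along y: symmetric about any x
  center_x <- (41 - 1) * 0.04 / 2
  # mirror the tissue about the electrode's x-coordinate
  fm <- f
  idx <- as.vector(t(matrix(seq_len(41 * 41), 41, 41, byrow = TRUE)[, 41:1]))
  fm$vm <- f$vm[, idx]
  phi <- compute_pegm(f, c(center_x, 0.6, 0.1))
  phim <- compute_pegm(fm, c(center_x, 0.6, 0.1))
  expect_equal(phi, phim, tolerance = 1e-12)
})

test_that("dimensional electrode averages the punctual EGMs of its nodes", {
  spec <- phantom_spec(nx = 41, ny = 41, dx = 0.02, t_total = 250)
  f <- phantom_vm(spec)
  center <- c(0.4, 0.4); z <- 0.1
  dim_egm <- compute_dimensional_egm(f, center, z, "square")
  # independent recomputation: mean over the 25 covered nodes (0.8 mm
  # footprint at 0.2 mm spacing)
  xs <- (seq_len(41) - 1) * 0.02
  cov <- xs[abs(xs - 0.4) <= 0.0400001]
  expect_equal(length(cov)^2, 25)
  acc <- 0
  for (x in cov) for (y in cov) acc <- acc + compute_pegm(f, c(x, y, z))
  expect_equal(dim_egm, acc / 25, tolerance = 1e-12)
  # punctual footprint reduces to the point electrogram
  expect_equal(compute_dimensional_egm(f, center, z, "punctual"),
               compute_pegm(f, c(center, z)), tolerance = 1e-15)
  expect_error(compute_dimensional_egm(f, c(0, 0), z, "square"), "footprint")
})

test_that("normalization applies the distance-specific factors", {
  f <- phantom_vm(phantom_spec(nx = 31, ny = 31, dx = 0.04, t_total = 200))
  for (zf in list(c(0.5, 350), c(1, 250), c(2, 150))) {
    g <- electrode_grid(f, n_rows = 2, n_cols = 2, z_mm = zf[1])
    e <- compute_egm_grid(f, g)
    en <- normalize_egm(e)
    expect_equal(en$phi, e$phi / zf[2])
  }
  g3 <- electrode_grid(f, n_rows = 2, n_cols = 2, z_mm = 1.5)
  e3 <- compute_egm_grid(f, g3)
  expect_error(normalize_egm(e3), "factor")
  expect_equal(normalize_egm(e3, factor = 200)$phi, e3$phi / 200)
  zero <- e3; zero$phi[] <- 0
  expect_true(all(normalize_egm(zero, factor = 250)$phi == 0))
})

test_that("zero-phase filters reject DC and shape the band as specified", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)[-1]
  # constant offset through the 2 Hz high-pass vanishes
  hp <- filter_egm(rep(3.5, length(t)), "hp2", fs = fs)
  expect_lt(max(abs(hp)), 1e-6)
  gain_at <- function(freq, band) {
    x <- sin(2 * pi * freq * t)
    y <- filter_egm(x, band, fs = fs)
    core <- seq(round(0.5 * fs), round(1.5 * fs))   # avoid edge transients
    sqrt(mean(y[core]^2) / mean(x[core]^2))
  }
  expect_lt(20 * log10(gain_at(1, "bp2_30")), -3)     # 1 Hz attenuated
  expect_gt(20 * log10(gain_at(10, "bp2_30")), -1)    # 10 Hz passed
  expect_gt(20 * log10(gain_at(100, "bp2_250")), -1)  # wide band passes 100 Hz
  expect_error(filter_egm(rep(0, 10), "hp2", fs = fs), "short")
})

test_that("wide-band filtering preserves the depolarization amplitude", {
  f <- phantom_vm(phantom_spec(nx = 41, ny = 61, dx = 0.04, t_total = 500))
  g <- electrode_grid(f, n_rows = 3, n_cols = 3, z_mm = 1)
  e <- normalize_egm(compute_egm_grid(f, g))
  ef <- filter_egm(e, "bp2_250")
  # compare peak-to-peak of the depolarization complex (first 150 ms)
  sel <- e$t <= 150
  p2p <- function(m) apply(m[sel, , drop = FALSE], 2, function(x) diff(range(x)))
  expect_equal(p2p(ef$phi), p2p(e$phi), tolerance = 0.05)
})

test_that("noise injection realizes the requested SNR per electrode", {
  f <- phantom_vm(phantom_spec(nx = 41, ny = 41, dx = 0.04, t_total = 500))
  g <- electrode_grid(f, n_rows = 3, n_cols = 3, z_mm = 1)
  e <- normalize_egm(compute_egm_grid(f, g))
  for (snr in c(0, 10, 20)) {
    noisy <- add_noise(e, snr, seed = 31)
    p_noise <- colMeans((noisy$phi - e$phi)^2)
    p_sig <- colMeans(e$phi^2)
    expect_equal(10 * log10(p_sig / p_noise), rep(snr, 9), tolerance = 0.05)
  }
  expect_identical(add_noise(e, Inf)$phi, e$phi)
  expect_identical(add_noise(e, NULL)$phi, e$phi)
  n1 <- add_noise(e, 10, seed = 5); n2 <- add_noise(e, 10, seed = 5)
  expect_identical(n1$phi, n2$phi)
  zero <- e; zero$phi[] <- 0
  expect_error(add_noise(zero, 10), "zero-power")
})
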