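# Monodomain solver: quiescence, conservation, planar propagation, CV.

test_that("unstimulated tissue stays at rest", {
  tis <- tissue_model(nx = 21, ny = 21, dx = 0.04)
  f <- simulate_tissue(tis, pacing_protocol(n_beats = 1, stim_amp = 0),
                       record_ms = 1000, prepace_s = 30)
  drift <- max(abs(sweep(f$vm, 2, f$vm[1, ])))
  expect_lt(drift, 1)
})

test_that("pure diffusion conserves the spatial mean under no-flux", {
  tis <- tissue_model(nx = 41, ny = 41, dx = 0.04)
  tis$label <- uniform_fibrosis(41, 41, 0.3, seed = 4)  # heterogeneous D
  set.seed(9)
  v0 <- matrix(runif(41 * 41, -90, 30), 41, 41)
  v1 <- run_diffusion(v0, tis, dt = 0.01, n_steps = 10000)  # 100 ms
  expect_lt(abs(mean(v1) - mean(v0)) / abs(mean(v0)), 1e-4)
  expect_lt(sd(v1), sd(v0))   # diffusion smooths
})

test_that("bottom-edge pacing yields a planar wavefront along the fiber", {
  tis <- tissue_model(nx = 31, ny = 51, dx = 0.04)
  f <- simulate_tissue(tis, pacing_protocol(n_beats = 1), record_ms = 120,
                       sample_dt = 0.5, prepace_s = 30)
  act <- activation_map(f)
  interior <- act[5:47, 4:28]
  # activation advances monotonically with y ...
  row_t <- apply(interior, 1, median)
  expect_true(all(diff(row_t) > 0))
  # ... and is flat along x away from the borders
  expect_lt(max(apply(interior, 1, function(r) diff(range(r)))), 1.01)
})

test_that("conduction velocity recovers a constructed wave speed", {
  spec <- phantom_spec(nx = 40, ny = 120, dx = 0.04, cv = 50, t_total = 140,
                       sample_dt = 0.5)
  f <- phantom_vm(spec)
  expect_equal(conduction_velocity(f), 50, tolerance = 0.03)
  # quiescent movie: all nodes unactivated, CV not measurable
  fq <- f; fq$vm[] <- -80
  expect_true(all(is.na(activation_map(fq))))
  expect_error(conduction_velocity(fq), "no activation")
})

test_that("CV scales with diffusion: PsAF slower, transverse ratio sqrt(0.5)", {
  strip <- function(d_long, dx = 0.04) {
    tis <- tissue_model(nx = round(0.32 / dx) + 1, ny = round(3 / dx) + 1,
                        dx = dx, d_long = d_long)
    f <- simulate_tissue(tis, pacing_protocol(n_beats = 1), record_ms = 95,
                         sample_dt = 0.1, prepace_s = 30)
    conduction_velocity(f)
  }
  cv_non <- strip(0.003)
  cv_ps <- strip(0.002)
  expect_lt(cv_ps, cv_non)
  # planar wave along y against transverse-valued diffusion emulates
  # propagation across fibers; monodomain scaling predicts CV ~ sqrt(D).
  # measured at dx 0.02 where the slower wavefront is resolved
  ratio <- strip(0.5 * 0.003, dx = 0.02) / strip(0.003, dx = 0.02)
  expect_equal(ratio, sqrt(0.5), tolerance = 0.05)
})

test_that("solver is deterministic and aborts on out-of-range potentials", {
  tis <- tissue_model(nx = 15, ny = 15, dx = 0.04)
  pac <- pacing_protocol(n_beats = 1)
  f1 <- simulate_tissue(tis, pac, record_ms = 50, prepace_s = 10)
  f2 <- simulate_tissue(tis, pac, record_ms = 50, prepace_s = 10)
  expect_identical(f1$vm, f2$vm)
  expect_error(
    simulate_tissue(tis, pacing_protocol(n_beats = 1, stim_amp = 500),
                    record_ms = 20, prepace_s = 10),
    "out of range")
})
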