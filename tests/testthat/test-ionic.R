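# Ionic models: parameter handling, IKACh, right-hand sides, single-cell
# pacing behavior.

test_that("remodeling conditions rescale the stated conductances", {
  base <- ionic_params()
  ps <- apply_condition(base, "PsAF")
  expect_equal(c(ps$scale_gto, ps$scale_gCaL, ps$scale_gKur),
               c(0.5, 0.3, 0.5))
  expect_equal(ps$scale_gK1, 1)
  expect_identical(apply_condition(base, "nonAF"), base)
  expect_identical(apply_condition(base, "PxAF"), base)
  expect_error(apply_condition(base, "chronic"), "unknown condition")
})

test_that("conductance variability grid is the Cartesian product of levels", {
  expect_equal(nrow(variability_grid()), 25)
  g0 <- variability_grid(0)
  expect_equal(nrow(g0), 1)
  expect_equal(unlist(g0), c(scale_gK1 = 1, scale_gCaL = 1))
  expect_equal(nrow(variability_grid(c(-30, 30))), 4)
})

test_that("IKACh: zero without agonist, reverses at EK, monotone in dose", {
  expect_equal(ikach(-40, 0, -85), 0)
  expect_equal(ikach(20, 0, -85), 0)
  expect_equal(ikach(-85, 0.1, -85), 0)
  expect_gt(abs(ikach(-40, 0.1, -85)), abs(ikach(-40, 0.01, -85)))
  # strictly increasing magnitude across a dose ladder at fixed vm != ek
  doses <- c(0.005, 0.01, 0.05, 0.1, 0.5)
  mags <- abs(vapply(doses, function(a) ikach(-60, a, -85), numeric(1)))
  expect_true(all(diff(mags) > 0))
  # sign flips across the reversal potential
  expect_lt(ikach(-95, 0.1, -85) * ikach(-75, 0.1, -85), 0)
  expect_error(ikach(-40, -0.1, -85), "non-negative")
})

test_that("myocyte RHS is near zero at rest and deterministic", {
  p <- ionic_params()
  # settle to rest: unstimulated integration from published conditions
  r <- pace_cell(p, n_beats = 5, stim_amp = 0, record_beats = 1)
  dy <- myocyte_rhs(r$state, p)
  expect_lt(abs(dy[["vm"]]), 1e-3)
  # bitwise determinism of the RHS
  st <- crn_initial_state()
  expect_identical(myocyte_rhs(st, p), myocyte_rhs(st, p))
  expect_error(myocyte_rhs(replace(st, 1, NaN), p), "blow-up")
})

test_that("PsAF remodeling scales ICaL to 0.3x at identical state", {
  st <- crn_initial_state()
  st[["vm"]] <- 0; st[["d"]] <- 0.6; st[["f"]] <- 0.7  # mid-AP-like state
  d_base <- myocyte_rhs(st, ionic_params())
  d_low <- myocyte_rhs(st, ionic_params(scale_gCaL = 0.3))
  ical <- 0.12375 * st[["d"]] * st[["f"]] * st[["fca"]] * (st[["vm"]] - 65)
  # only ICaL differs between the two parameter sets
  expect_equal(d_low[["vm"]] - d_base[["vm"]], -(0.3 - 1) * ical,
               tolerance = 1e-10)
})

test_that("fibroblast rests depolarized, responds to injected current", {
  pf <- ionic_params(model_variant = "fibroblast")
  rest <- steady_state_init(pf, duration_s = 20)
  dy <- fibroblast_rhs(rest)
  expect_lt(abs(dy[["vm"]]), 1e-3)
  expect_gt(fibroblast_rhs(rest, coupling_current = 5)[["vm"]], 0)
  # depolarized relative to the myocyte resting potential
  myo_rest <- pace_cell(ionic_params(), n_beats = 5, stim_amp = 0,
                        record_beats = 1)$state
  expect_gt(rest[["vm"]], myo_rest[["vm"]] + 20)
})

test_that("gates stay in [0,1] and concentrations positive during pacing", {
  r <- pace_cell(ionic_params(ach_uM = 0.1), n_beats = 3, record_beats = 1)
  expect_true(all(is.finite(r$vm)))
  st <- r$state
  expect_true(all(st[2:16] >= 0 & st[2:16] <= 1))
  expect_true(all(st[17:21] > 0))
})

test_that("steady-state initialization converges and respects duration 0", {
  expect_identical(steady_state_init(ionic_params(), duration_s = 0),
                   crn_initial_state())
  st <- steady_state_init(ionic_params(), duration_s = 30, cache = FALSE)
  expect_true(attr(st, "converged"))
  expect_gt(attr(st, "apd90"), 200)
})

test_that("fast integrator agrees with an independent stiff ODE solution", {
  skip_if_not_installed("deSolve")
  p <- ionic_params()
  # one paced beat from published initial conditions, both routes
  rhs_desolve <- function(t, y, parms) {
    stim <- if (t <= 2) 20 else 0
    y[2:16] <- pmin(pmax(y[2:16], 0), 1)   # lsoda may overshoot gate bounds
    list(as.numeric(myocyte_rhs(setNames(y, names(crn_initial_state())),
                                p, t, i_stim = stim)))
  }
  sol <- deSolve::lsoda(as.numeric(crn_initial_state()),
                        seq(0, 500, by = 0.5), rhs_desolve, NULL,
                        rtol = 1e-6, atol = 1e-8)
  apd_ref <- apd90(sol[, 2], sol[, 1])
  r <- pace_cell(p, n_beats = 1, record_beats = 1)
  sel <- r$t >= 0 & r$t <= 500
  apd_fast <- apd90(r$vm[sel], r$t[sel])
  expect_equal(apd_fast, apd_ref, tolerance = 0.02)
})

test_that("acetylcholine dose-dependently shortens the action potential", {
  apd_at <- function(ach) {
    r <- pace_cell(ionic_params(ach_uM = ach), n_beats = 40)
    sel <- r$t >= 0
    apd90(r$vm[sel], r$t[sel])
  }
  a0 <- apd_at(0); a05 <- apd_at(0.05); a1 <- apd_at(0.1)
  expect_gt(a0, a05)
  expect_gt(a05, a1)
  # persistent-AF remodeling also shortens APD at matched (zero) dose
  rps <- pace_cell(apply_condition(ionic_params(), "PsAF"), n_beats = 40)
  sel <- rps$t >= 0
  expect_lt(apd90(rps$vm[sel], rps$t[sel]), a0)
})
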