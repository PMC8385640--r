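# Explicit finite-difference monodomain solver on a tissue lattice.

#' Edge pacing protocol
#'
#' @param cl Cycle length (ms).
#' @param n_beats Number of paced beats; the last beat is recorded.
#' @param stim_amp Stimulus amplitude (pA/pF, depolarizing positive). The
#'   default is twice the diastolic threshold of the non-AF tissue as found
#'   by [diastolic_threshold()].
#' @param stim_dur Stimulus duration (ms).
#' @param depth Stimulated rows at the bottom edge (full width).
#' @return Object of class `pacing_protocol`.
#' @export
pacing_protocol <- function(cl = 1000, n_beats = 2, stim_amp = 40,
                            stim_dur = 2, depth = 2) {
  if (!(cl > stim_dur && stim_dur > 0)) stop("need cl > stim_dur > 0")
  structure(list(cl = cl, n_beats = as.integer(n_beats), stim_amp = stim_amp,
                 stim_dur = stim_dur, depth = as.integer(depth)),
            class = "pacing_protocol")
}

# per-node parameter vectors and initial states for a tissue
tissue_node_setup <- function(tissue, condition = tissue$condition,
                              variability = NULL, cl = 1000,
                              prepace_s = 60, seed = NULL) {
  n <- tissue$nx * tissue$ny
  lab <- as.integer(t(tissue$label))   # row-major: node n = (i-1)*nx + j
  ach <- as.numeric(t(tissue$ach))
  base <- apply_condition(ionic_params(), condition)
  sg <- list(gto = rep(base$scale_gto, n), gcal = rep(base$scale_gCaL, n),
             gkur = rep(base$scale_gKur, n), gk1 = rep(base$scale_gK1, n))
  combo <- rep(1L, n)
  if (!is.null(variability)) {
    combo <- with_seed(seed, sample.int(nrow(variability), n, replace = TRUE))
    sg$gk1 <- sg$gk1 * variability$scale_gK1[combo]
    sg$gcal <- sg$gcal * variability$scale_gCaL[combo]
  }
  states <- matrix(0, 21, n)
  fib_state <- steady_state_init(ionic_params(model_variant = "fibroblast"),
                                 cl = cl, duration_s = min(prepace_s, 20))
  dach <- numeric(n)
  keys <- paste(ach, combo, lab)
  for (k in unique(keys)) {
    idx <- which(keys == k)
    n1 <- idx[1]
    if (lab[n1] == 1L) {
      states[1:3, idx] <- as.numeric(fib_state)
    } else {
      p <- base
      p$ach_uM <- ach[n1]
      if (!is.null(variability)) {
        p$scale_gK1 <- sg$gk1[n1]
        p$scale_gCaL <- sg$gcal[n1]
      }
      st <- steady_state_init(p, cl = cl, duration_s = prepace_s)
      states[, idx] <- as.numeric(st)
      if (ach[n1] > 0) dach[idx] <- ikach_dose_factor_cpp(ach[n1])
    }
  }
  list(label = lab, states = states, sg = sg, dach = dach)
}

#' Solve the monodomain equation on a tissue
#'
#' Explicit finite differences: flux-form 5-point Laplacian with the
#' edge-wise diffusion map from [build_diffusion()], Rush-Larsen integration
#' of voltage gates, forward Euler elsewhere, no-flux boundaries. The time
#' step adapts between `dt[1]` and `dt[2]` based on the maximal |dVm/dt| of
#' the previous step. All nodes are initialized from single-cell steady
#' states matching their type, acetylcholine dose and conductance scalings.
#'
#' @param tissue [tissue_model()].
#' @param pacing [pacing_protocol()]; stimuli at the bottom edge.
#' @param dt Fixed step (ms) or adaptive range `c(lo, hi)`.
#' @param record_ms Duration of the recorded movie from the last stimulus
#'   (default one full cycle).
#' @param sample_dt Movie sampling interval (ms).
#' @param variability Optional tibble from [variability_grid()] assigning
#'   random IK1/ICaL conductance combinations to nodes.
#' @param prepace_s Single-cell pre-pacing duration (s) for initial states.
#' @param seed RNG seed for the variability assignment.
#' @return Object of class `achmap_vm`: list with `vm` (frames x nodes
#'   matrix), `t` (ms from last stimulus), grid geometry and metadata.
#' @export
simulate_tissue <- function(tissue, pacing = pacing_protocol(),
                            dt = c(0.005, 0.01), record_ms = NULL,
                            sample_dt = 1, variability = NULL,
                            prepace_s = 60, seed = NULL) {
  stopifnot(inherits(tissue, "achmap_tissue"),
            inherits(pacing, "pacing_protocol"))
  dt <- rep(dt, length.out = 2)
  if (is.null(record_ms)) record_ms <- pacing$cl
  dmap <- build_diffusion(tissue)
  setup <- tissue_node_setup(tissue, variability = variability,
                             cl = pacing$cl, prepace_s = prepace_s,
                             seed = seed)
  nx <- tissue$nx; ny <- tissue$ny
  stim_nodes <- as.integer(outer(0:(pacing$depth - 1) * nx, 0:(nx - 1), `+`))
  rec_from <- (pacing$n_beats - 1) * pacing$cl
  t_total <- rec_from + record_ms
  r <- integrate_tissue_cpp(setup$label, setup$states,
                            setup$sg$gto, setup$sg$gcal, setup$sg$gkur,
                            setup$sg$gk1, setup$dach,
                            nx, ny, as.numeric(t(dmap$Dx)),
                            as.numeric(t(dmap$Dy)), tissue$dx,
                            stim_nodes, pacing$stim_amp, pacing$stim_dur,
                            pacing$cl, pacing$n_beats, t_total,
                            dt[1], dt[2], 20, rec_from, sample_dt)
  structure(list(vm = r$vm, t = r$t, nx = nx, ny = ny, dx = tissue$dx,
                 sample_dt = sample_dt, source = "monodomain",
                 condition = tissue$condition, nsteps = r$nsteps,
                 dt_mean = r$dt_mean, final_state = r$state),
            class = "achmap_vm")
}

#' @export
print.achmap_vm <- function(x, ...) {
  cat(sprintf("<achmap_vm %s: %d frames x %d nodes (%d x %d), dx %.3g cm, dt %g ms>\n",
              x$source, nrow(x$vm), ncol(x$vm), x$nx, x$ny, x$dx, x$sample_dt))
  invisible(x)
}

#' Membrane potential trace of one node
#'
#' @param field `achmap_vm`; `i`, `j` node row and column (1-based; node
#'   index is `(i-1)*nx + j`).
#' @return Numeric Vm waveform (mV).
#' @export
vm_trace <- function(field, i, j) field$vm[, (i - 1) * field$nx + j]

#' Per-node activation times
#'
#' Activation time of each node as the time of maximal dVm/dt of its trace.
#' Nodes whose upstroke velocity never exceeds `min_slope` or whose peak
#' stays below `min_peak` are flagged unactivated (NA).
#'
#' @param field `achmap_vm` movie.
#' @param min_slope mV/ms; `min_peak` mV.
#' @return Matrix (`ny` x `nx`) of times (ms), NA where unactivated.
#' @export
activation_map <- function(field, min_slope = 5, min_peak = -40) {
  stopifnot(inherits(field, "achmap_vm"))
  dv <- diff(field$vm) / field$sample_dt
  idx <- max.col(t(dv), ties.method = "first")
  slope <- dv[cbind(idx, seq_len(ncol(dv)))]
  peak <- apply(field$vm, 2, max)
  act <- field$t[idx]
  act[slope < min_slope | peak < min_peak] <- NA_real_
  matrix(act, field$ny, field$nx, byrow = TRUE)
}

#' Conduction velocity of a planar wave
#'
#' Activation-time difference between two interior probe lines separated by
#' a known distance along the propagation axis.
#'
#' @param field `achmap_vm` with a planar wave along `axis`.
#' @param axis Propagation axis (`"y"` is the fiber direction).
#' @param probes Fractional positions of the two probe lines.
#' @return CV in cm/s.
#' @export
conduction_velocity <- function(field, axis = c("y", "x"),
                                probes = c(0.25, 0.75)) {
  axis <- match.arg(axis)
  act <- activation_map(field)
  n_along <- if (axis == "y") field$ny else field$nx
  rows <- pmax(2, pmin(n_along - 1, round(probes * n_along)))
  line_time <- function(k) {
    v <- if (axis == "y") act[k, ] else act[, k]
    v <- v[seq(3, length(v) - 2)]          # drop lateral borders
    if (all(is.na(v))) stop("no activation detected at probe line ", k)
    median(v, na.rm = TRUE)
  }
  t1 <- line_time(rows[1]); t2 <- line_time(rows[2])
  if (!is.finite(t1) || !is.finite(t2) || t2 == t1)
    stop("no propagation between probe lines")
  (rows[2] - rows[1]) * field$dx / (t2 - t1) * 1000
}

#' Diastolic stimulation threshold by bisection
#'
#' Finds the minimal bottom-edge stimulus amplitude that elicits a
#' propagated response (activation at mid-tissue) on the given tissue, by
#' bisection on a short single-beat simulation.
#'
#' @param tissue [tissue_model()]; a small strip is enough.
#' @param lo,hi Initial bracket (pA/pF); keep `hi` moderate, a very
#'   strong stimulus drives the edge nodes outside the solver's Vm range.
#' @param tol Bisection tolerance (pA/pF).
#' @param sim_ms Simulated duration per trial.
#' @param prepace_s Pre-pacing of the initial states (s).
#' @return Threshold amplitude (pA/pF).
#' @export
diastolic_threshold <- function(tissue, lo = 5, hi = 60, tol = 1,
                                sim_ms = 80, prepace_s = 60) {
  captured <- function(amp) {
    pac <- pacing_protocol(cl = 1000, n_beats = 1, stim_amp = amp)
    f <- simulate_tissue(tissue, pac, record_ms = sim_ms,
                         prepace_s = prepace_s)
    mid <- vm_trace(f, round(tissue$ny / 2), round(tissue$nx / 2))
    max(mid) > 0
  }
  if (captured(lo)) return(lo)
  if (!captured(hi)) stop("upper bracket does not capture")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (captured(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Pure diffusion step (no membrane kinetics)
#'
#' Advances an arbitrary Vm profile under the tissue's diffusion map alone;
#' used to verify conservation and no-flux boundary handling.
#'
#' @param v0 Initial profile, `ny` x `nx` matrix (mV).
#' @param tissue [tissue_model()].
#' @param dt Step (ms); `n_steps` number of steps.
#' @return Final profile matrix.
#' @export
run_diffusion <- function(v0, tissue, dt = 0.01, n_steps = 1000) {
  stopifnot(inherits(tissue, "achmap_tissue"),
            nrow(v0) == tissue$ny, ncol(v0) == tissue$nx)
  dmap <- build_diffusion(tissue)
  out <- diffuse_cpp(as.numeric(t(v0)), tissue$nx, tissue$ny,
                     as.numeric(t(dmap$Dx)), as.numeric(t(dmap$Dy)),
                     tissue$dx, dt, as.integer(n_steps))
  matrix(out, tissue$ny, tissue$nx, byrow = TRUE)
}
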