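# Ionic model surface: parameter containers, conditions, single-cell dynamics.

CRN_STATE_NAMES <- c("vm", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
                     "d", "f", "fca", "u", "v", "w", "nai", "ki", "cai",
                     "caup", "carel")
FIB_STATE_NAMES <- c("vm", "r", "s")

#' Ionic parameter set for a single cell
#'
#' Bundles the conductance scalings, acetylcholine dose and cell variant used
#' by the Courtemanche myocyte model (with IKACh) or the MacCannell active
#' fibroblast model.
#'
#' @param scale_gto,scale_gCaL,scale_gKur,scale_gK1 Dimensionless multipliers
#'   of the maximal conductances of Ito, ICaL, IKur and IK1 (all > 0,
#'   default 1).
#' @param ach_uM Acetylcholine concentration in micromolar (>= 0). Activates
#'   IKACh; 0 disables it.
#' @param cm Membrane capacitance (pF). Informational; currents are expressed
#'   per unit capacitance.
#' @param model_variant `"myocyte"` or `"fibroblast"`.
#' @return An object of class `ionic_params`.
#' @export
#' @examples
#' p <- ionic_params(ach_uM = 0.1)
#' apply_condition(p, "PsAF")
ionic_params <- function(scale_gto = 1, scale_gCaL = 1, scale_gKur = 1,
                         scale_gK1 = 1, ach_uM = 0, cm = 100,
                         model_variant = c("myocyte", "fibroblast")) {
  model_variant <- match.arg(model_variant)
  scales <- c(scale_gto, scale_gCaL, scale_gKur, scale_gK1)
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("conductance scalings must be positive")
  if (!is.finite(ach_uM) || ach_uM < 0)
    stop("ach_uM must be non-negative")
  structure(list(scale_gto = scale_gto, scale_gCaL = scale_gCaL,
                 scale_gKur = scale_gKur, scale_gK1 = scale_gK1,
                 ach_uM = ach_uM, cm = cm, model_variant = model_variant),
            class = "ionic_params")
}

#' @export
print.ionic_params <- function(x, ...) {
  cat(sprintf("<ionic_params: %s, ACh %g uM, scales gto %g gCaL %g gKur %g gK1 %g>\n",
              x$model_variant, x$ach_uM, x$scale_gto, x$scale_gCaL,
              x$scale_gKur, x$scale_gK1))
  invisible(x)
}

#' Apply an atrial-fibrillation remodeling condition
#'
#' Persistent-AF electrical remodeling reduces Ito by 50%, ICaL by 70% and
#' IKur by 50%. Non-AF and paroxysmal-AF substrates leave the single-cell
#' electrophysiology unchanged (they differ at tissue level through fibrosis
#' and coupling).
#'
#' @param params An [ionic_params()] object.
#' @param condition One of `"nonAF"`, `"PxAF"`, `"PsAF"`.
#' @return Modified `ionic_params`.
#' @export
apply_condition <- function(params, condition) {
  stopifnot(inherits(params, "ionic_params"))
  if (length(condition) != 1 || !condition %in% c("nonAF", "PxAF", "PsAF"))
    stop("unknown condition: ", paste(condition, collapse = ", "))
  if (condition == "PsAF") {
    params$scale_gto  <- params$scale_gto  * 0.5
    params$scale_gCaL <- params$scale_gCaL * 0.3
    params$scale_gKur <- params$scale_gKur * 0.5
  }
  params
}

#' Cell-to-cell variability grid for IK1 and ICaL conductances
#'
#' Cartesian product of percentage offsets applied to the IK1 and ICaL
#' maximal conductances, used to populate tissues with electrophysiologically
#' distinct cells. The default five levels from -30% to +30% in 15% steps
#' give 25 combinations.
#'
#' @param levels Numeric vector of percentage offsets.
#' @return A tibble with columns `scale_gK1` and `scale_gCaL` (multipliers).
#' @export
#' @examples
#' nrow(variability_grid())  # 25
variability_grid <- function(levels = c(-30, -15, 0, 15, 30)) {
  if (length(levels) == 0) stop("levels must be non-empty")
  g <- expand.grid(gk1 = 1 + levels / 100, gcal = 1 + levels / 100)
  tibble::tibble(scale_gK1 = g$gk1, scale_gCaL = g$gcal)
}

#' Acetylcholine-activated potassium current
#'
#' Kneller-type formulation: a dose-dependent conductance
#' `g_max / (1 + 9.13652 / ach^0.477811)` (nS/pF, `ach` in micromolar) times
#' a voltage-dependent factor `0.0517 + 0.4516 / (1 + exp((vm + 59.53)/17.18))`
#' and the potassium driving force `vm - ek`. The maximal conductance is
#' set to 1.8 nS/pF (the original guinea-pig-derived dose-response shape is
#' retained) so that a 0.1 micromolar dose shortens the human atrial APD90
#' by about one half -- a moderate cholinergic response -- rather than
#' collapsing it; see the methods vignette.
#'
#' @param vm Membrane potential (mV).
#' @param ach_uM Acetylcholine concentration (micromolar, >= 0).
#' @param ek Potassium reversal potential (mV).
#' @return Current in pA/pF (vectorized over `vm`).
#' @export
#' @examples
#' ikach(-80, 0.1, -85)
#' ikach(-85, 0.1, -85)  # zero at the reversal potential
ikach <- function(vm, ach_uM, ek) {
  if (!is.finite(ach_uM) || ach_uM < 0) stop("ach_uM must be non-negative")
  k <- ikach_constants()
  g <- if (ach_uM == 0) 0 else k$g_max / (1 + k$k_half / ach_uM^k$hill)
  vfac <- k$c1 + k$c2 / (1 + exp((vm + k$v_half) / k$v_slope))
  g * vfac * (vm - ek)
}

#' IKACh constants table
#'
#' The pinned constants of the IKACh formulation used throughout the package.
#' @return Named list.
#' @export
ikach_constants <- function() {
  list(g_max = 1.8, k_half = 9.13652, hill = 0.477811,
       c1 = 0.0517, c2 = 0.4516, v_half = 59.53, v_slope = 17.18)
}

#' Published initial conditions of the Courtemanche myocyte model
#'
#' @return Named numeric vector of the 21 state variables (mV, gating
#'   fractions, mM).
#' @export
crn_initial_state <- function() {
  setNames(c(-81.18, 0.002908, 0.9649, 0.9775, 0.03043, 0.9992, 0.004966,
             0.9986, 3.296e-5, 0.01869, 1.367e-4, 0.9996, 0.7755, 0, 1,
             0.9992, 11.17, 139.0, 1.013e-4, 1.488, 1.488),
           CRN_STATE_NAMES)
}

#' Initial conditions of the MacCannell fibroblast model
#'
#' @return Named numeric vector (vm in mV, Kv gates r and s).
#' @export
fibroblast_initial_state <- function() {
  setNames(c(-49.6, 0.05, 0.9), FIB_STATE_NAMES)
}

check_cell_state <- function(state, variant) {
  nm <- if (variant == "myocyte") CRN_STATE_NAMES else FIB_STATE_NAMES
  if (length(state) != length(nm))
    stop("state must have ", length(nm), " elements for a ", variant)
  if (any(!is.finite(state)))
    stop("non-finite state variable: numerical blow-up?")
  gates <- if (variant == "myocyte") 2:16 else 2:3
  if (any(state[gates] < -1e-9) || any(state[gates] > 1 + 1e-9))
    stop("gating variables must lie in [0, 1]")
  if (variant == "myocyte" && any(state[17:21] <= 0))
    stop("intracellular concentrations must be positive")
  invisible(TRUE)
}

#' Time derivatives of the Courtemanche myocyte state
#'
#' Full right-hand side of the Courtemanche human atrial model, including
#' IKACh when the parameter set carries a positive acetylcholine dose.
#'
#' @param state Named numeric vector as from [crn_initial_state()].
#' @param params An [ionic_params()] object (myocyte variant).
#' @param t Time (ms); the model is autonomous, kept for solver interfaces.
#' @param i_stim Stimulus current (pA/pF, depolarizing positive).
#' @return Named vector of d(state)/dt.
#' @export
myocyte_rhs <- function(state, params = ionic_params(), t = 0, i_stim = 0) {
  stopifnot(inherits(params, "ionic_params"))
  check_cell_state(state, "myocyte")
  dy <- crn_rhs_cpp(as.numeric(state),
                    c(params$scale_gto, params$scale_gCaL,
                      params$scale_gKur, params$scale_gK1),
                    params$ach_uM, i_stim)
  setNames(dy, CRN_STATE_NAMES)
}

#' Time derivatives of the MacCannell fibroblast state
#'
#' @param state Named numeric vector as from [fibroblast_initial_state()].
#' @param params Ignored (kept for interface symmetry).
#' @param coupling_current Injected current (pA/pF, depolarizing positive),
#'   e.g. gap-junctional current from a coupled myocyte.
#' @return Named vector of d(state)/dt.
#' @export
fibroblast_rhs <- function(state, params = NULL, coupling_current = 0) {
  check_cell_state(state, "fibroblast")
  dy <- fib_rhs_cpp(as.numeric(state), coupling_current)
  setNames(dy, FIB_STATE_NAMES)
}

# --------------------------------------------------------------------------
# single-cell pacing
# --------------------------------------------------------------------------

cell_cache <- new.env(parent = emptyenv())

#' Pace a single cell and record membrane potential
#'
#' Integrates one cell with the package's Rush-Larsen/forward-Euler scheme,
#' applying periodic stimulation, and records the membrane potential over the
#' final beats.
#'
#' @param params [ionic_params()].
#' @param cl Cycle length (ms).
#' @param n_beats Number of paced beats.
#' @param dt Time step (ms) or range `c(lo, hi)` for the adaptive controller.
#' @param stim_amp Stimulus amplitude (pA/pF), `stim_dur` duration (ms).
#' @param record_beats How many final beats to record.
#' @param sample_dt Recording interval (ms).
#' @return List with `vm`, `t` (ms, relative to the last stimulus; earlier
#'   beats have negative times) and `state` (final named state vector).
#' @export
pace_cell <- function(params, cl = 1000, n_beats = 60, dt = c(0.005, 0.01),
                      stim_amp = 20, stim_dur = 2, record_beats = 2,
                      sample_dt = 0.5) {
  stopifnot(inherits(params, "ionic_params"))
  if (cl <= stim_dur || stim_dur <= 0) stop("need cl > stim_dur > 0")
  myo <- params$model_variant == "myocyte"
  y0 <- if (myo) crn_initial_state() else
    c(fibroblast_initial_state(), numeric(18))
  st <- matrix(as.numeric(y0), ncol = 1)
  dt <- rep(dt, length.out = 2)
  dur <- n_beats * cl
  rec_from <- max(0, dur - record_beats * cl)
  one <- 1
  dach <- if (myo && params$ach_uM > 0) ikach_dose_factor_cpp(params$ach_uM) else 0
  r <- integrate_tissue_cpp(if (myo) 0L else 1L, st,
                            params$scale_gto * one, params$scale_gCaL * one,
                            params$scale_gKur * one, params$scale_gK1 * one,
                            dach * one, 1L, 1L, numeric(0), numeric(0), 0.02,
                            0L, stim_amp, stim_dur, cl, as.integer(n_beats),
                            dur, dt[1], dt[2], 20, rec_from, sample_dt)
  nm <- if (myo) CRN_STATE_NAMES else FIB_STATE_NAMES
  state <- setNames(r$state[seq_along(nm), 1], nm)
  list(vm = r$vm[, 1], t = r$t, state = state)
}

#' Action potential duration at 90% repolarization
#'
#' @param vm Membrane potential trace (mV) of a single beat starting just
#'   before the upstroke.
#' @param t Sample times (ms).
#' @return APD90 in ms (NA if the trace does not repolarize to 90%).
#' @export
apd90 <- function(vm, t) {
  stopifnot(length(vm) == length(t), length(vm) > 3)
  v_rest <- vm[1]
  up <- which.max(diff(vm))
  v_peak <- max(vm[up:length(vm)])
  v90 <- v_peak - 0.9 * (v_peak - v_rest)
  after <- which(seq_along(vm) > up & vm < v90)
  if (length(after) == 0) return(NA_real_)
  i <- after[1]
  # linear interpolation between samples for sub-sample resolution
  t_cross <- t[i - 1] + (v90 - vm[i - 1]) / (vm[i] - vm[i - 1]) * (t[i] - t[i - 1])
  t_cross - t[up]
}

#' Pace a cell to steady state
#'
#' Pace at a fixed cycle length until the periodic steady state is reached
#' (default one minute of pacing), returning the final state used to
#' initialize tissue nodes. Convergence is checked as a relative APD90
#' difference below `tol` between the two final beats; a warning is raised
#' otherwise. Fibroblasts are relaxed to their own resting state without
#' stimulation.
#'
#' @param params [ionic_params()].
#' @param cl Cycle length (ms).
#' @param duration_s Pacing duration (s). `0` returns the published initial
#'   conditions unchanged.
#' @param tol Relative APD90 convergence tolerance.
#' @param cache Reuse previously computed steady states for identical
#'   parameters within the session.
#' @return Named state vector with attributes `apd90` (ms) and `converged`.
#' @export
steady_state_init <- function(params, cl = 1000, duration_s = 60, tol = 0.01,
                              cache = TRUE) {
  stopifnot(inherits(params, "ionic_params"))
  if (cl <= 0) stop("cl must be positive")
  if (duration_s == 0) {
    return(if (params$model_variant == "myocyte") crn_initial_state()
           else fibroblast_initial_state())
  }
  key <- paste(params$model_variant, params$scale_gto, params$scale_gCaL,
               params$scale_gKur, params$scale_gK1, params$ach_uM, cl,
               duration_s, sep = "|")
  if (cache && !is.null(cell_cache[[key]])) return(cell_cache[[key]])

  if (params$model_variant == "fibroblast") {
    r <- pace_cell(params, cl = cl, n_beats = max(1, round(duration_s * 1000 / cl)),
                   stim_amp = 0, record_beats = 1)
    out <- r$state
    attr(out, "apd90") <- NA_real_
    attr(out, "converged") <- TRUE
  } else {
    n_beats <- max(2, round(duration_s * 1000 / cl))
    r <- pace_cell(params, cl = cl, n_beats = n_beats, record_beats = 2)
    last <- r$t >= 0
    prev <- r$t >= -cl & r$t < 0
    a_last <- apd90(r$vm[last], r$t[last])
    a_prev <- apd90(r$vm[prev], r$t[prev] + cl)
    conv <- is.finite(a_last) && is.finite(a_prev) &&
      abs(a_last - a_prev) / a_prev < tol
    if (!conv)
      warning(sprintf(paste0("steady_state_init: APD90 not converged ",
                             "(last two beats %.1f / %.1f ms)"), a_prev, a_last))
    out <- r$state
    attr(out, "apd90") <- a_last
    attr(out, "converged") <- conv
  }
  if (cache) cell_cache[[key]] <- out
  out
}
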