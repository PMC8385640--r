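# Analytic phantoms: planar-wave action-potential movies with ACh and
# fibrosis zones, and the band-limited unit-power noise source. These make
# the electrogram and detection stages testable in seconds without solving
# the tissue equations.

#' Phantom specification
#'
#' A planar wave of template action potentials travels along the fiber (y)
#' axis at a constant velocity. The template has a fast linear upstroke, a
#' slowly declining plateau and a logistic phase-3 repolarization whose
#' midpoint sets the action potential duration and whose time constant sets
#' the phase-3 steepness. Acetylcholine zones shorten the duration and
#' accelerate phase 3 (which is what raises their electrogram repolarization
#' amplitude); fibrotic zones depress the upstroke amplitude and delay local
#' activation.
#'
#' @param nx,ny,dx Grid dimensions (nodes) and spacing (cm).
#' @param cv Conduction velocity (cm/s).
#' @param t_total Movie duration (ms); `sample_dt` sampling interval (ms).
#' @param rest,amp Resting potential and AP amplitude (mV).
#' @param apd,phase3_tau Baseline AP duration (ms) and phase-3 time constant
#'   (ms).
#' @param ach_apd,ach_phase3_tau The same inside acetylcholine zones.
#' @param ach_zones,fibro_zones Tibbles of circles (`x`, `y`, `r` in cm).
#' @param fibro_amp_factor Upstroke amplitude factor in fibrotic zones.
#' @param fibro_delay Extra activation delay in fibrotic zones (ms).
#' @return Object of class `phantom_spec` carrying a ground-truth `registry`.
#' @export
phantom_spec <- function(nx = 100, ny = 100, dx = 0.04, cv = 60,
                         t_total = 600, sample_dt = 1,
                         rest = -80, amp = 105,
                         apd = 300, phase3_tau = 14,
                         ach_apd = 190, ach_phase3_tau = 5,
                         ach_zones = NULL, fibro_zones = NULL,
                         fibro_amp_factor = 0.55, fibro_delay = 10) {
  if (cv <= 0) stop("cv must be positive")
  if (ach_apd >= apd) stop("ACh zones must have shorter APD than baseline")
  empty <- tibble::tibble(x = numeric(), y = numeric(), r = numeric())
  if (is.null(ach_zones)) ach_zones <- empty
  if (is.null(fibro_zones)) fibro_zones <- empty
  reg <- dplyr::bind_rows(
    if (nrow(ach_zones)) tibble::tibble(kind = "ACh", x = ach_zones$x,
                                        y = ach_zones$y, r = ach_zones$r,
                                        dose = 0.1),
    if (nrow(fibro_zones)) tibble::tibble(kind = "fibrosis", x = fibro_zones$x,
                                          y = fibro_zones$y, r = fibro_zones$r,
                                          dose = NA_real_))
  if (is.null(reg)) reg <- tibble::tibble(kind = character(), x = numeric(),
                                          y = numeric(), r = numeric(),
                                          dose = numeric())
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx, cv = cv,
                 t_total = t_total, sample_dt = sample_dt, rest = rest,
                 amp = amp, apd = apd, phase3_tau = phase3_tau,
                 ach_apd = ach_apd, ach_phase3_tau = ach_phase3_tau,
                 ach_zones = ach_zones, fibro_zones = fibro_zones,
                 fibro_amp_factor = fibro_amp_factor,
                 fibro_delay = fibro_delay, registry = reg),
            class = "phantom_spec")
}

in_any_circle <- function(x, y, circles) {
  if (nrow(circles) == 0) return(rep(FALSE, length(x)))
  Reduce(`|`, lapply(seq_len(nrow(circles)), function(k)
    sqrt((x - circles$x[k])^2 + (y - circles$y[k])^2) <= circles$r[k]))
}

#' Generate a phantom Vm movie
#'
#' @param spec [phantom_spec()].
#' @param seed Unused (the phantom is deterministic); kept for interface
#'   uniformity with the simulators.
#' @return `achmap_vm` with `source = "phantom"` and the spec's registry
#'   attached (so [ground_truth()] and [detect_ach()] work directly).
#' @export
phantom_vm <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$nx; ny <- spec$ny
  xn <- rep((seq_len(nx) - 1) * spec$dx, times = ny)
  yn <- rep((seq_len(ny) - 1) * spec$dx, each = nx)
  ach <- in_any_circle(xn, yn, spec$ach_zones)
  fib <- in_any_circle(xn, yn, spec$fibro_zones)
  t_act <- yn / spec$cv * 1000 + ifelse(fib, spec$fibro_delay, 0)
  apd_n <- ifelse(ach, spec$ach_apd, spec$apd)
  tau_n <- ifelse(ach, spec$ach_phase3_tau, spec$phase3_tau)
  amp_n <- spec$amp * ifelse(fib, spec$fibro_amp_factor, 1)
  t <- seq(0, spec$t_total, by = spec$sample_dt)
  tau <- outer(t, t_act, `-`)                       # frames x nodes
  up <- pmin(pmax(tau, 0), 1)                       # 1 ms linear upstroke
  plateau <- 1 - 0.55 * (1 - exp(-pmax(tau, 0) / 80))
  repol <- 1 / (1 + exp(sweep(sweep(tau, 2, apd_n), 2, tau_n, `/`)))
  vm <- spec$rest + sweep(up * plateau * repol, 2, amp_n, `*`)
  structure(list(vm = vm, t = t, nx = nx, ny = ny, dx = spec$dx,
                 sample_dt = spec$sample_dt, source = "phantom",
                 condition = "phantom", registry = spec$registry,
                 spec = spec),
            class = "achmap_vm")
}

#' Band-limited unit-power synthetic noise
#'
#' Gaussian noise spectrally shaped to the given band with a 1/f^alpha
#' weighting, zero mean, normalized to unit empirical power. A synthetic
#' stand-in for patient-derived electrogram noise segments.
#'
#' @param n Number of samples.
#' @param sample_dt Sampling interval (ms).
#' @param band Passband `c(lo, hi)` in Hz.
#' @param seed Optional RNG seed.
#' @param alpha Spectral tilt exponent (0 = flat).
#' @return Numeric vector with `mean(x^2) == 1`.
#' @export
synth_noise <- function(n, sample_dt = 1, band = c(1, 100), seed = NULL,
                        alpha = 0.5) {
  fs <- 1000 / sample_dt
  nyq <- fs / 2
  if (band[1] < 0 || band[2] <= band[1]) stop("invalid noise band")
  if (band[2] > nyq) stop("noise band exceeds the Nyquist frequency")
  with_seed(seed, {
    w <- rnorm(n)
    W <- fft(w)
    f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
    h <- ifelse(abs(f) >= band[1] & abs(f) <= band[2],
                1 / pmax(abs(f), band[1])^alpha, 0)
    x <- Re(fft(W * h, inverse = TRUE)) / n
    x <- x - mean(x)
    p <- mean(x^2)
    if (p == 0) stop("noise band infeasible for this signal length")
    x / sqrt(p)
  })
}
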