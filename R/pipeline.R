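# Configuration-driven orchestration: condition x fibrosis x ACh geometry
# x electrode distance x noise, with threshold tables and sweeps.

#' Simulation scale profiles
#'
#' `full_profile()` reproduces the reference geometry: 5 x 5 cm tissue
#' (251 x 251 nodes, dx 0.02 cm), a 16 x 16 electrode grid at 2 mm pitch,
#' two paced beats with the second analyzed. `desk_profile()` is the
#' reduced-scale configuration used by the test-suite and the acceptance
#' runs: 2 x 2 cm (51 x 51 nodes, dx 0.04 cm), an 8 x 8 electrode
#' grid, one analyzed beat of 550 ms, and fewer ACh circles per geometry
#' (chosen to keep the in-grid ACh area fraction comparable to full scale).
#' All algorithmic behavior is identical between profiles.
#'
#' @param ... Overrides of individual profile fields.
#' @return List of profile settings.
#' @export
desk_profile <- function(...) {
  p <- list(nx = 51, ny = 51, dx = 0.04,
            n_rows = 8, n_cols = 8, pitch_mm = 2,
            n_beats = 1, record_ms = 550, sample_dt = 1,
            dt = c(0.005, 0.01), prepace_s = 60, stim_amp = 40,
            ach_counts = list(r032 = 3, r050 = 1, r076 = 1, mixed = c(1, 2)),
            min_separation = 0.04)
  utils::modifyList(p, list(...))
}

#' @rdname desk_profile
#' @export
full_profile <- function(...) {
  p <- list(nx = 251, ny = 251, dx = 0.02,
            n_rows = 16, n_cols = 16, pitch_mm = 2,
            n_beats = 2, record_ms = 1000, sample_dt = 1,
            dt = c(0.005, 0.01), prepace_s = 60, stim_amp = 40,
            ach_counts = list(r032 = 6, r050 = 3, r076 = 2, mixed = c(2, 3)),
            min_separation = 0.05)
  utils::modifyList(p, list(...))
}

ach_radii <- function(geometry) {
  switch(geometry,
         r032 = 0.32, r050 = 0.5, r076 = 0.76,
         mixed = c(0.5, 0.24),
         stop("unknown ACh geometry: ", geometry))
}

fibrosis_spec <- function(fibrosis) {
  switch(fibrosis,
         none    = list(type = "none", density = 0),
         Fu20    = list(type = "uniform", density = 0.2),
         Fu40    = list(type = "uniform", density = 0.4),
         Fnu1_20 = list(type = "patchy", layout = "Fnu1", density = 0.2),
         Fnu2_20 = list(type = "patchy", layout = "Fnu2", density = 0.2),
         Fnu1_40 = list(type = "patchy", layout = "Fnu1", density = 0.4),
         Fnu2_40 = list(type = "patchy", layout = "Fnu2", density = 0.4),
         stop("unknown fibrosis pattern: ", fibrosis))
}

#' Experiment configuration
#'
#' Validates a single cell of the experiment matrix. The substrate pairings
#' are enforced (non-AF has no fibrosis, paroxysmal AF carries 20% fibrosis,
#' persistent AF 40% plus electrical remodeling and reduced coupling) unless
#' explicitly overridden.
#'
#' @param condition `"nonAF"`, `"PxAF"` or `"PsAF"`.
#' @param fibrosis `"none"`, `"Fu20"`, `"Fu40"`, `"Fnu1_20"`, `"Fnu2_20"`,
#'   `"Fnu1_40"`, `"Fnu2_40"`.
#' @param ach_geometry `"r032"`, `"r050"`, `"r076"` or `"mixed"` (0.5 +
#'   0.24 cm circles).
#' @param z_mm Electrode-tissue distance (mm).
#' @param snr_db Noise level (dB) or `NULL` for clean signals.
#' @param seed RNG seed controlling fibrosis and patch placement.
#' @param profile [desk_profile()] or [full_profile()].
#' @param allow_mismatch Permit condition/fibrosis pairings outside the
#'   standard matrix.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(condition, fibrosis, ach_geometry = "r050",
                              z_mm = 1, snr_db = NULL, seed = 1,
                              profile = desk_profile(),
                              allow_mismatch = FALSE) {
  if (!condition %in% c("nonAF", "PxAF", "PsAF"))
    stop("unknown condition: ", condition)
  fs <- fibrosis_spec(fibrosis)   # validates
  ach_radii(ach_geometry)         # validates
  allowed <- switch(condition,
                    nonAF = "none",
                    PxAF = c("Fu20", "Fnu1_20", "Fnu2_20"),
                    PsAF = c("Fu40", "Fnu1_40", "Fnu2_40"))
  if (!fibrosis %in% allowed && !allow_mismatch)
    stop(condition, " is paired with ", paste(allowed, collapse = "/"),
         " fibrosis; got ", fibrosis,
         " (set allow_mismatch = TRUE to override)")
  structure(list(condition = condition, fibrosis = fibrosis,
                 fibrosis_spec = fs, ach_geometry = ach_geometry,
                 z_mm = z_mm, snr_db = snr_db, seed = as.integer(seed),
                 profile = profile),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config %s / %s / %s, z %g mm, %s, seed %d>\n",
              x$condition, x$fibrosis, x$ach_geometry, x$z_mm,
              if (is.null(x$snr_db)) "clean" else paste0("SNR ", x$snr_db, " dB"),
              x$seed))
  invisible(x)
}

#' Build the tissue of a configuration
#'
#' @param config [experiment_config()].
#' @return `achmap_tissue` with fibrosis labels, ACh patches and registry.
#' @export
build_config_tissue <- function(config) {
  p <- config$profile
  d_long <- if (config$condition == "PsAF") 0.002 else 0.003
  tis <- tissue_model(nx = p$nx, ny = p$ny, dx = p$dx, d_long = d_long,
                      condition = config$condition)
  fs <- config$fibrosis_spec
  if (fs$type == "uniform") {
    tis$label <- uniform_fibrosis(p$nx, p$ny, fs$density,
                                  seed = config$seed * 1000L + 1L)
  } else if (fs$type == "patchy") {
    tis <- add_fibrotic_patches(tis, fnu_preset(tis, fs$layout), fs$density,
                                seed = config$seed * 1000L + 1L)
  }
  radii <- ach_radii(config$ach_geometry)
  counts <- p$ach_counts[[config$ach_geometry]]
  # centers constrained to the electrode-mapped central area
  lx <- (p$nx - 1) * p$dx
  half_x <- (p$n_cols - 1) * p$pitch_mm / 10 / 2
  half_y <- (p$n_rows - 1) * p$pitch_mm / 10 / 2
  region <- c(lx / 2 - half_x, lx / 2 + half_x,
              lx / 2 - half_y, lx / 2 + half_y)
  place_ach_patches(tis, radii = radii, n_per_radius = counts,
                    region = region, min_separation = p$min_separation,
                    seed = config$seed * 1000L + 2L)
}

#' Run one experiment configuration end to end
#'
#' Builds the tissue, paces it with the monodomain solver (or accepts a
#' precomputed movie), computes the electrode-grid EGMs, normalizes and
#' filters them, optionally injects noise, and runs the detection algorithm
#' with ROC-optimized thresholds.
#'
#' For clean signals both detection stages read the 2 Hz high-passed EGMs;
#' for noisy signals repolarization analysis uses the 2-30 Hz band-pass and
#' depolarization analysis the 2-250 Hz band-pass, as in clinical practice.
#'
#' @param config [experiment_config()].
#' @param field Optional precomputed `achmap_vm` (e.g. a phantom) to skip
#'   the solver.
#' @param keep Character vector of heavyweight artifacts to retain in the
#'   result: any of `"field"`, `"egm"`.
#' @return Object of class `achmap_run`: the config, tissue, detection, a
#'   one-row `summary` tibble, and retained artifacts.
#' @export
run_experiment <- function(config, field = NULL, keep = "egm") {
  stopifnot(inherits(config, "experiment_config"))
  p <- config$profile
  tis <- build_config_tissue(config)
  if (is.null(field)) {
    pac <- pacing_protocol(cl = 1000, n_beats = p$n_beats,
                           stim_amp = p$stim_amp)
    field <- simulate_tissue(tis, pac, dt = p$dt, record_ms = p$record_ms,
                             sample_dt = p$sample_dt,
                             prepace_s = p$prepace_s)
  }
  grid <- electrode_grid(tis, n_rows = p$n_rows, n_cols = p$n_cols,
                         pitch_mm = p$pitch_mm, z_mm = config$z_mm)
  egm_raw <- compute_egm_grid(field, grid)
  egm_clean <- filter_egm(normalize_egm(egm_raw), "hp2")
  det <- detect_run(egm_raw, tis, config)
  out <- list(config = config, tissue = tis, detection = det,
              egm = if ("egm" %in% keep) egm_raw else NULL,
              field = if ("field" %in% keep) field else NULL,
              summary = run_summary(config, det))
  class(out) <- "achmap_run"
  out
}

# detection stage from the raw (unnormalized, unfiltered) EGM grid.
# The SNR of injected noise is referenced to the grid-level power of the
# clean repolarization window: the noise is calibrated against the wave
# the detector reads, giving the microvolt noise amplitudes of clinical
# repolarization analysis rather than millivolt amplitudes tied to the
# much larger depolarization complex.
detect_run <- function(egm_raw, tissue, config) {
  egm_n <- normalize_egm(egm_raw)
  egm_f <- filter_egm(egm_n, "hp2")
  if (is.null(config$snr_db) || !is.finite(config$snr_db %||% Inf)) {
    detect_ach(egm_f, tissue)
  } else {
    w <- delineate(egm_f)
    sel <- egm_f$t >= w$tw_on & egm_f$t <= w$tw_off
    p_repol <- mean(egm_f$phi[sel, , drop = FALSE]^2)
    noisy <- add_noise(egm_n, config$snr_db,
                       seed = config$seed * 1000L + 3L,
                       p_signal = p_repol)
    detect_ach(filter_egm(noisy, "bp2_30"), tissue,
               egm_depol = filter_egm(noisy, "bp2_250"))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_summary <- function(config, det) {
  g <- glance(det)
  tibble::tibble(condition = config$condition, fibrosis = config$fibrosis,
                 ach_geometry = config$ach_geometry, z_mm = config$z_mm,
                 snr_db = config$snr_db %||% NA_real_, seed = config$seed,
                 mode = g$mode, ac = g$ac, se = g$se, fpr = g$fpr,
                 r_th_pct = g$r_th_pct, d_th_pct = g$d_th_pct,
                 r_th_fibro_pct = g$r_th_fibro_pct)
}

#' @export
print.achmap_run <- function(x, ...) {
  cat("<achmap_run>\n"); print(x$summary); invisible(x)
}

#' Threshold table across configurations
#'
#' Optimal thresholds per (fibrosis x ACh geometry) cell, expressed as
#' percentages of the grid maxima, with row and column means — fibrotic-
#' region repolarization thresholds (possibly negative) alongside the
#' non-fibrotic ones.
#'
#' @param runs List of `achmap_run` objects (or their `summary` rows bound
#'   into a tibble).
#' @return Tibble with one row per configuration plus `Mean` rows.
#' @export
threshold_table <- function(runs) {
  tab <- if (inherits(runs, "data.frame")) runs else
    dplyr::bind_rows(lapply(runs, `[[`, "summary"))
  cell <- tab |>
    dplyr::group_by(.data$fibrosis, .data$ach_geometry) |>
    dplyr::summarise(r_th_pct = mean(.data$r_th_pct),
                     r_th_fibro_pct = mean(.data$r_th_fibro_pct),
                     d_th_pct = mean(.data$d_th_pct), .groups = "drop")
  means <- cell |>
    dplyr::group_by(.data$fibrosis) |>
    dplyr::summarise(ach_geometry = "Mean",
                     r_th_pct = mean(.data$r_th_pct),
                     r_th_fibro_pct = mean(.data$r_th_fibro_pct),
                     d_th_pct = mean(.data$d_th_pct), .groups = "drop")
  dplyr::bind_rows(cell, means)
}

#' Robustness sweep along noise or electrode distance
#'
#' Re-runs the detection stage of a completed run across an axis of SNR
#' values (reusing the clean EGMs, so differences are attributable to the
#' noise alone) or electrode-tissue distances (recomputing the forward
#' model from the retained Vm movie).
#'
#' @param run `achmap_run` with the needed artifact retained (`"egm"` for
#'   the SNR axis, `"field"` for the z axis).
#' @param axis `"snr"` or `"z"`.
#' @param values Axis values: dB levels or z in mm. Empty gives an empty
#'   table.
#' @return Tibble with one summary row per axis value.
#' @export
robustness_sweep <- function(run, axis = c("snr", "z"),
                             values = if (axis == "snr") c(0, 5, 10, 15, 20)
                                      else c(0.5, 1, 2)) {
  axis <- match.arg(axis)
  stopifnot(inherits(run, "achmap_run"))
  if (length(values) == 0) return(run$summary[0, ])
  rows <- lapply(values, function(v) {
    cfg <- run$config
    if (axis == "snr") {
      if (is.null(run$egm)) stop("run must retain the EGM grid (keep = 'egm')")
      cfg$snr_db <- v
      det <- detect_run(run$egm, run$tissue, cfg)
    } else {
      if (is.null(run$field)) stop("run must retain the Vm movie (keep = 'field')")
      cfg$z_mm <- v
      p <- cfg$profile
      grid <- electrode_grid(run$tissue, n_rows = p$n_rows,
                             n_cols = p$n_cols, pitch_mm = p$pitch_mm,
                             z_mm = v)
      det <- detect_run(compute_egm_grid(run$field, grid), run$tissue, cfg)
    }
    run_summary(cfg, det)
  })
  dplyr::bind_rows(rows)
}
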