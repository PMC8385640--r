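# Unipolar electrogram forward model: dipole-kernel summation over the
# tissue, electrode footprint averaging, normalization, filtering, noise.

#' Extracellular electrode grid
#'
#' A regular grid of unipolar electrodes centered over the tissue at height
#' `z` above the sheet. Dimensional electrodes average the punctual EGMs of
#' all nodes covered by their square footprint.
#'
#' @param tissue [tissue_model()] (or any object with `nx`, `ny`, `dx`).
#' @param n_rows,n_cols Electrode counts (default 16 x 16).
#' @param pitch_mm Inter-electrode spacing (mm).
#' @param z_mm Electrode-tissue distance (mm); 0.5, 1 or 2 for the standard
#'   normalization factors.
#' @param footprint `"square"` (0.8 x 0.8 mm, averaged over covered nodes)
#'   or `"punctual"`.
#' @param footprint_mm Side of the square footprint (mm).
#' @return Object of class `electrode_grid`: tibble of electrode positions
#'   (cm) with geometry attributes.
#' @export
electrode_grid <- function(tissue, n_rows = 16, n_cols = 16, pitch_mm = 2,
                           z_mm = 1, footprint = c("square", "punctual"),
                           footprint_mm = 0.8) {
  footprint <- match.arg(footprint)
  if (z_mm <= 0) stop("z must be positive")
  pitch <- pitch_mm / 10; z <- z_mm / 10          # cm
  lx <- (tissue$nx - 1) * tissue$dx
  ly <- (tissue$ny - 1) * tissue$dx
  cx <- lx / 2; cy <- ly / 2
  xs <- cx + (seq_len(n_cols) - (n_cols + 1) / 2) * pitch
  ys <- cy + (seq_len(n_rows) - (n_rows + 1) / 2) * pitch
  if (min(xs) < 0 || max(xs) > lx || min(ys) < 0 || max(ys) > ly)
    stop("electrode grid does not project inside the tissue")
  g <- tidyr::expand_grid(row = seq_len(n_rows), col = seq_len(n_cols))
  g$x <- xs[g$col]; g$y <- ys[g$row]
  structure(g, class = c("electrode_grid", class(g)),
            n_rows = n_rows, n_cols = n_cols, pitch = pitch, z = z,
            footprint = footprint, footprint_cm = footprint_mm / 10)
}

# spatial gradients of the Vm movie, one-sided at borders (mV/cm)
egm_gradients <- function(field) {
  nx <- field$nx; ny <- field$ny
  dxcm <- field$dx
  j <- rep(seq_len(nx), times = ny)   # node n = (i-1)*nx + j
  i <- rep(seq_len(ny), each = nx)
  n_of <- function(ii, jj) (ii - 1) * nx + jj
  jp <- pmin(j + 1, nx); jm <- pmax(j - 1, nx * 0 + 1)
  ip <- pmin(i + 1, ny); im <- pmax(i - 1, 1)
  wx <- 1 / ((jp - jm) * dxcm)
  wy <- 1 / ((ip - im) * dxcm)
  Gx <- (field$vm[, n_of(i, jp)] - field$vm[, n_of(i, jm)]) *
    rep(wx, each = nrow(field$vm))
  Gy <- (field$vm[, n_of(ip, j)] - field$vm[, n_of(im, j)]) *
    rep(wy, each = nrow(field$vm))
  list(Gx = Gx, Gy = Gy)
}

# dipole-kernel weights for one observation point (cm-based, area weighted)
egm_kernel <- function(field, xe, ye, ze) {
  nx <- field$nx; ny <- field$ny
  xn <- rep((seq_len(nx) - 1) * field$dx, times = ny)
  yn <- rep((seq_len(ny) - 1) * field$dx, each = nx)
  dxcm <- field$dx
  ex <- xn - xe; ey <- yn - ye
  d <- sqrt(ex^2 + ey^2 + ze^2)
  w <- dxcm^2 / d^3
  list(kx = ex * w, ky = ey * w)
}

#' Punctual unipolar electrogram at an arbitrary point
#'
#' Evaluates the current-dipole integral over the whole sheet: the movie's
#' spatial Vm gradient (central differences, one-sided at borders) dotted
#' with the analytic gradient of `1/d` to the observation point, summed with
#' area weights.
#'
#' @param field `achmap_vm` movie.
#' @param r_prime Observation point `c(x, y, z)` in cm (z > 0 above sheet).
#' @param gradients Optional precomputed [egm_gradients()] result.
#' @return Numeric waveform (one value per movie frame, arbitrary units
#'   until [normalize_egm()]).
#' @export
compute_pegm <- function(field, r_prime, gradients = NULL) {
  stopifnot(inherits(field, "achmap_vm"), length(r_prime) == 3)
  if (r_prime[3] <= 0) stop("electrode height z must be positive (singular kernel)")
  if (is.null(gradients)) gradients <- egm_gradients(field)
  k <- egm_kernel(field, r_prime[1], r_prime[2], r_prime[3])
  drop(gradients$Gx %*% k$kx + gradients$Gy %*% k$ky)
}

#' Dimensional (finite-footprint) unipolar electrogram
#'
#' Average of the punctual EGMs at all nodes covered by the electrode's
#' square footprint (25 nodes for a 0.8 mm electrode at 0.2 mm node
#' spacing).
#'
#' @param field `achmap_vm`.
#' @param center `c(x, y)` electrode center (cm); `z` height (cm).
#' @param footprint `"square"` or `"punctual"`.
#' @param footprint_cm Footprint side (cm).
#' @param gradients Optional precomputed gradients.
#' @return Numeric waveform.
#' @export
compute_dimensional_egm <- function(field, center, z,
                                    footprint = c("square", "punctual"),
                                    footprint_cm = 0.08, gradients = NULL) {
  footprint <- match.arg(footprint)
  if (footprint == "punctual")
    return(compute_pegm(field, c(center, z), gradients))
  half <- footprint_cm / 2 + 1e-9
  xs <- (seq_len(field$nx) - 1) * field$dx
  ys <- (seq_len(field$ny) - 1) * field$dx
  jj <- which(abs(xs - center[1]) <= half)
  ii <- which(abs(ys - center[2]) <= half)
  if (length(jj) == 0 || length(ii) == 0 ||
      center[1] - half < -1e-9 || center[1] + half > max(xs) + 1e-9 ||
      center[2] - half < -1e-9 || center[2] + half > max(ys) + 1e-9)
    stop("electrode footprint exceeds the tissue")
  if (is.null(gradients)) gradients <- egm_gradients(field)
  pts <- tidyr::expand_grid(x = xs[jj], y = ys[ii])
  acc <- 0
  for (k in seq_len(nrow(pts)))
    acc <- acc + compute_pegm(field, c(pts$x[k], pts$y[k], z), gradients)
  acc / nrow(pts)
}

#' Compute the full electrogram grid
#'
#' Forward-computes the unipolar EGM of every electrode of the grid from a
#' Vm movie. For dimensional electrodes the footprint average is folded into
#' the kernel (the forward model is linear in the kernel weights).
#'
#' @param field `achmap_vm`.
#' @param grid [electrode_grid()].
#' @return Object of class `achmap_egm`: `phi` (frames x electrodes matrix,
#'   electrodes in grid row-major order), `t`, the grid, and processing
#'   metadata.
#' @export
compute_egm_grid <- function(field, grid) {
  stopifnot(inherits(field, "achmap_vm"), inherits(grid, "electrode_grid"))
  gr <- egm_gradients(field)
  z <- attr(grid, "z")
  fp <- attr(grid, "footprint")
  half <- attr(grid, "footprint_cm") / 2 + 1e-9
  xs <- (seq_len(field$nx) - 1) * field$dx
  ys <- (seq_len(field$ny) - 1) * field$dx
  nE <- nrow(grid)
  Kx <- matrix(0, field$nx * field$ny, nE)
  Ky <- matrix(0, field$nx * field$ny, nE)
  for (e in seq_len(nE)) {
    if (fp == "punctual") {
      k <- egm_kernel(field, grid$x[e], grid$y[e], z)
      Kx[, e] <- k$kx; Ky[, e] <- k$ky
    } else {
      jj <- xs[abs(xs - grid$x[e]) <= half]
      ii <- ys[abs(ys - grid$y[e]) <= half]
      pts <- tidyr::expand_grid(x = jj, y = ii)
      for (p in seq_len(nrow(pts))) {
        k <- egm_kernel(field, pts$x[p], pts$y[p], z)
        Kx[, e] <- Kx[, e] + k$kx / nrow(pts)
        Ky[, e] <- Ky[, e] + k$ky / nrow(pts)
      }
    }
  }
  phi <- gr$Gx %*% Kx + gr$Gy %*% Ky
  structure(list(phi = phi, t = field$t, grid = grid,
                 n_rows = attr(grid, "n_rows"), n_cols = attr(grid, "n_cols"),
                 sample_dt = field$sample_dt, z_mm = z * 10,
                 normalized = FALSE, filter = "none", noise = "none"),
            class = "achmap_egm")
}

#' @export
print.achmap_egm <- function(x, ...) {
  cat(sprintf("<achmap_egm %d x %d electrodes, %d frames, z %g mm, filter %s, noise %s>\n",
              x$n_rows, x$n_cols, nrow(x$phi), x$z_mm, x$filter, x$noise))
  invisible(x)
}

#' Distance-dependent EGM normalization
#'
#' Scales raw forward-model output to the clinical millivolt range by a
#' factor depending on the electrode-tissue distance: 350 for z = 0.5 mm,
#' 250 for z = 1 mm, 150 for z = 2 mm.
#'
#' @param egm `achmap_egm`.
#' @param z_mm Distance (mm); defaults to the grid's.
#' @param factor Explicit divisor overriding the distance lookup.
#' @return Normalized `achmap_egm` (phi in mV).
#' @export
normalize_egm <- function(egm, z_mm = egm$z_mm, factor = NULL) {
  stopifnot(inherits(egm, "achmap_egm"))
  if (is.null(factor)) {
    factors <- c("0.5" = 350, "1" = 250, "2" = 150)
    key <- as.character(z_mm)
    if (!key %in% names(factors))
      stop("no normalization factor for z = ", z_mm,
           " mm; supply `factor` explicitly")
    factor <- factors[[key]]
  }
  egm$phi <- egm$phi / factor
  egm$normalized <- TRUE
  egm$norm_factor <- factor
  egm
}

butter_filter <- function(band, fs) {
  nyq <- fs / 2
  switch(band,
         hp2     = signal::butter(4, 2 / nyq, type = "high"),
         bp2_30  = signal::butter(2, c(2, 30) / nyq, type = "pass"),
         bp2_250 = signal::butter(2, c(2, min(250, nyq * 0.999)) / nyq,
                                  type = "pass"),
         stop("unknown band: ", band))
}

# forward-backward filtering with odd-reflection padding so edge transients
# do not leak into the signal (scipy-style). The mean is removed first: all
# bands used here reject DC, and demeaning kills the dominant startup
# transient of the low cutoff exactly.
filtfilt_pad <- function(bt, x) {
  n <- length(x)
  x <- x - mean(x)
  p <- min(n - 1, 500)
  left <- 2 * x[1] - x[(p + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- signal::filtfilt(bt, c(left, x, right))
  y[(p + 1):(p + n)]
}

#' Zero-phase EGM filtering
#'
#' Forward-backward Butterworth filtering: a 2 Hz high-pass (`hp2`, DC
#' removal as in clinical mapping systems), a 2-30 Hz band-pass (`bp2_30`,
#' repolarization analysis of noisy signals) or a 2-250 Hz band-pass
#' (`bp2_250`, depolarization analysis).
#'
#' @param egm `achmap_egm` or a plain numeric waveform.
#' @param band One of `"hp2"`, `"bp2_30"`, `"bp2_250"`.
#' @param fs Sampling rate (Hz); taken from the object when omitted.
#' @return Filtered object of the same type.
#' @export
filter_egm <- function(egm, band = c("hp2", "bp2_30", "bp2_250"), fs = NULL) {
  band <- match.arg(band)
  if (inherits(egm, "achmap_egm")) {
    fs <- 1000 / egm$sample_dt
    if (nrow(egm$phi) < 24) stop("signal too short for stable filtering")
    bt <- butter_filter(band, fs)
    egm$phi <- apply(egm$phi, 2, function(x) filtfilt_pad(bt, x))
    egm$filter <- band
    return(egm)
  }
  if (is.null(fs)) stop("fs required for plain waveforms")
  if (length(egm) < 24) stop("signal too short for stable filtering")
  filtfilt_pad(butter_filter(band, fs), egm)
}

#' Add noise at a controlled signal-to-noise ratio
#'
#' Unit-power noise segments (by default the package's band-limited
#' synthetic noise) are scaled per electrode so that
#' `10*log10(P_signal / P_noise)` equals `snr_db`, with the signal power
#' measured on the clean waveform over the analyzed beat.
#'
#' @param egm `achmap_egm` (clean).
#' @param snr_db Target SNR in dB; `Inf` or `NULL` returns the input.
#' @param seed RNG seed (one stream for the whole grid).
#' @param noise_fun Generator `function(n, sample_dt, band, seed)` returning
#'   a unit-power segment; defaults to [synth_noise()].
#' @param band Noise band (Hz) passed to the generator.
#' @param p_signal Signal-power reference (mV^2): a scalar applied to every
#'   electrode or one value per electrode. Defaults to each electrode's
#'   mean square over the whole record; the experiment pipeline passes the
#'   grid-level power of the repolarization window instead, which matches
#'   the microvolt-scale noise amplitudes of clinical repolarization
#'   analysis.
#' @return Noisy `achmap_egm`.
#' @export
add_noise <- function(egm, snr_db, seed = NULL, noise_fun = synth_noise,
                      band = c(1, 100), p_signal = NULL) {
  stopifnot(inherits(egm, "achmap_egm"))
  if (is.null(snr_db) || !is.finite(snr_db)) return(egm)
  p_sig <- if (is.null(p_signal)) colMeans(egm$phi^2) else
    rep(p_signal, length.out = ncol(egm$phi))
  if (any(p_sig == 0)) stop("zero-power signal: cannot set an SNR")
  with_seed(seed, {
    for (e in seq_len(ncol(egm$phi))) {
      noise <- noise_fun(nrow(egm$phi), egm$sample_dt, band, seed = NULL)
      egm$phi[, e] <- egm$phi[, e] + noise * sqrt(p_sig[e] / 10^(snr_db / 10))
    }
  })
  egm$noise <- sprintf("snr %g dB", snr_db)
  egm
}

#' Electrogram grid as a tidy tibble
#'
#' @param x `achmap_egm`.
#' @param ... Unused.
#' @return Tibble with columns `row`, `col`, `t`, `phi`.
#' @export
tidy.achmap_egm <- function(x, ...) {
  nE <- ncol(x$phi)
  tibble::tibble(row = rep(x$grid$row, each = nrow(x$phi)),
                 col = rep(x$grid$col, each = nrow(x$phi)),
                 t = rep(x$t, nE),
                 phi = as.numeric(x$phi))
}

#' Export an electrogram grid to CSV
#'
#' One column per electrode (`e<row>_<col>`) plus time.
#' @param egm `achmap_egm`; `path` output file.
#' @return `path`, invisibly.
#' @export
write_egm_csv <- function(egm, path) {
  df <- as.data.frame(egm$phi)
  names(df) <- sprintf("e%d_%d", egm$grid$row, egm$grid$col)
  df <- cbind(t = egm$t, df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
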