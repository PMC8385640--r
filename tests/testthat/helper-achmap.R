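# Shared fixtures and independent brute-force oracles for the test suite.
# Oracles here deliberately re-derive results by enumeration / naive loops,
# independent of the package's optimized code paths.

# small random Vm movie (frames x nodes) wrapped as an achmap_vm
random_field <- function(nx = 30, ny = 30, nt = 12, dx = 0.04, seed = 1) {
  set.seed(seed)
  vm <- matrix(rnorm(nt * nx * ny, mean = -60, sd = 30), nt, nx * ny)
  structure(list(vm = vm, t = seq_len(nt) - 1, nx = nx, ny = ny, dx = dx,
                 sample_dt = 1, source = "phantom", condition = "test"),
            class = "achmap_vm")
}

# naive double-loop punctual EGM: same discretization contract, different code
brute_pegm <- function(field, r_prime) {
  nx <- field$nx; ny <- field$ny; dx <- field$dx
  nt <- nrow(field$vm)
  out <- numeric(nt)
  vm_at <- function(k, i, j) field$vm[k, (i - 1) * nx + j]
  for (k in seq_len(nt)) {
    acc <- 0
    for (i in seq_len(ny)) {
      for (j in seq_len(nx)) {
        jm <- max(j - 1, 1); jp <- min(j + 1, nx)
        im <- max(i - 1, 1); ip <- min(i + 1, ny)
        gx <- (vm_at(k, i, jp) - vm_at(k, i, jm)) / ((jp - jm) * dx)
        gy <- (vm_at(k, ip, j) - vm_at(k, im, j)) / ((ip - im) * dx)
        ex <- (j - 1) * dx - r_prime[1]
        ey <- (i - 1) * dx - r_prime[2]
        d <- sqrt(ex^2 + ey^2 + r_prime[3]^2)
        acc <- acc + (gx * ex + gy * ey) / d^3 * dx^2
      }
    }
    out[k] <- acc
  }
  out
}

# brute-force signed repolarization amplitude: collapse equal-value runs,
# call a run a local extremum if it beats both neighboring runs; earliest
# sample of the run is its location. Ties |min| = |max| resolve positive.
brute_repol <- function(x) {
  r <- rle(x)
  v <- r$values
  if (length(v) < 3) return(x[which.max(abs(x))])
  cand <- c()
  for (k in 2:(length(v) - 1)) {
    if ((v[k] > v[k - 1] && v[k] > v[k + 1]) ||
        (v[k] < v[k - 1] && v[k] < v[k + 1])) cand <- c(cand, v[k])
  }
  if (length(cand) == 0) return(x[which.max(abs(x))])
  lo <- min(cand); hi <- max(cand)
  if (abs(lo) > abs(hi)) lo else hi
}

# exhaustive midpoint-threshold ROC optimum (distance to the (0,1) corner)
brute_roc_best <- function(scores, truth, direction = "greater") {
  s <- sort(unique(scores))
  mids <- c(s[1] - 1, (head(s, -1) + tail(s, -1)) / 2, s[length(s)] + 1)
  best <- Inf; best_th <- NA
  for (th in mids) {
    pred <- if (direction == "greater") scores > th else scores < th
    se <- sum(pred & truth) / sum(truth)
    fpr <- sum(pred & !truth) / sum(!truth)
    d <- sqrt((1 - se)^2 + fpr^2)
    if (d < best) { best <- d; best_th <- th }
  }
  list(dist = best, threshold = best_th)
}

# small phantom with two ACh zones, reused across EGM/detection tests
ach_phantom <- function(nx = 80, ny = 80, fibro = FALSE) {
  phantom_spec(
    nx = nx, ny = ny, dx = 0.04,
    ach_zones = tibble::tibble(x = c(0.9, 2.2), y = c(1.0, 2.1),
                               r = c(0.42, 0.35)),
    fibro_zones = if (fibro)
      tibble::tibble(x = 2.0, y = 1.0, r = 0.5) else NULL)
}

# detection pipeline on an EGM grid coming from a phantom field
phantom_detect <- function(field, snr_db = NULL, n_rows = 10, n_cols = 10,
                           seed = 1) {
  grid <- electrode_grid(field, n_rows = n_rows, n_cols = n_cols,
                         pitch_mm = 2, z_mm = 1)
  egm <- normalize_egm(compute_egm_grid(field, grid))
  if (is.null(snr_db)) {
    detect_ach(filter_egm(egm, "hp2"), field)
  } else {
    noisy <- add_noise(egm, snr_db, seed = seed)
    detect_ach(filter_egm(noisy, "bp2_30"), field,
               egm_depol = filter_egm(noisy, "bp2_250"))
  }
}
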