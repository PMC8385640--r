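# Detection of acetylcholine-release sites from EGM amplitude maps:
# repolarization-window delineation, amplitude operators, ROC threshold
# optimization, two-stage fibrosis/ACh classification, metrics.

#' Automatic repolarization-window delineation
#'
#' The depolarization reference time `t_ref` (t = 0 of a case) is the median
#' over electrodes of each electrode's steepest-negative-slope time. The
#' grid-global repolarization peak time `t_R` is the time of the maximal
#' |phi| over all electrodes in a window starting 100 ms after `t_ref`; the
#' analysis window spans 30 ms before to 150 ms after `t_R`.
#'
#' @param egm `achmap_egm` with a shared time base.
#' @param search_from Offset of the `t_R` search start after `t_ref` (ms).
#' @param pre,post Window extent around `t_R` (ms).
#' @param onset_frac Fraction of the grid depolarization maximum defining
#'   the EGM onset (start of the depolarization segment).
#' @return Object of class `repol_window`: list with `t_ref`, `t_R`,
#'   `tw_on`, `tw_off`, `onset`, and the peak electrode (`im`, `jm`).
#' @export
delineate <- function(egm, search_from = 100, pre = 30, post = 150,
                      onset_frac = 0.05) {
  stopifnot(inherits(egm, "achmap_egm"))
  phi <- egm$phi; t <- egm$t
  slopes <- apply(phi, 2, function(x) t[which.min(diff(x))])
  t_ref <- median(slopes)
  in_search <- t >= t_ref + search_from
  if (!any(in_search)) stop("no samples after the repolarization search start")
  sub <- abs(phi[in_search, , drop = FALSE])
  depol_max <- max(abs(phi[t < t_ref + search_from, , drop = FALSE]))
  if (max(sub) < 1e-3 * depol_max || max(sub) == 0)
    stop("no repolarization peak found after the depolarization wave")
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  t_R <- t[in_search][pk[1]]
  e <- as.integer(pk[2])
  # EGM onset: first sample before t_ref where any |phi| exceeds the
  # stated fraction of the grid depolarization maximum
  pre_ref <- which(t < t_ref)
  amp_t <- apply(abs(phi), 1, max)
  on_idx <- pre_ref[amp_t[pre_ref] > onset_frac * depol_max]
  onset <- if (length(on_idx)) t[on_idx[1]] else t[1]
  structure(list(t_ref = t_ref, t_R = t_R, tw_on = t_R - pre,
                 tw_off = t_R + post, onset = onset,
                 im = egm$grid$row[e], jm = egm$grid$col[e]),
            class = "repol_window")
}

#' @export
print.repol_window <- function(x, ...) {
  cat(sprintf("<repol_window t_ref %.1f, t_R %.1f, TW [%.1f, %.1f] ms>\n",
              x$t_ref, x$t_R, x$tw_on, x$tw_off))
  invisible(x)
}

# indices of interior local extrema; plateaus resolve to their first sample
local_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2) return(integer(0))
  ext <- integer(0)
  for (k in seq_len(length(nz) - 1)) {
    if (s[nz[k]] != s[nz[k + 1]]) ext <- c(ext, nz[k] + 1)
  }
  # plateau: first sample after the rise/fall; shift to plateau start
  ext
}

#' Signed repolarization amplitude of one electrogram
#'
#' Among the local extrema of the waveform inside the repolarization window,
#' returns the one with the largest absolute value, sign preserved. An exact
#' |min| = |max| tie returns the positive value (positive peaks are the
#' acetylcholine signature) with attribute `tie = TRUE`.
#'
#' @param phi Waveform; `t` its sample times (ms).
#' @param window [delineate()] result (or any list with `tw_on`, `tw_off`).
#' @return Signed amplitude (same units as `phi`).
#' @export
repol_amplitude <- function(phi, t, window) {
  sel <- t >= window$tw_on & t <= window$tw_off
  if (!any(sel)) stop("empty repolarization window")
  x <- phi[sel]
  ext <- local_extrema(x)
  cand <- if (length(ext)) x[ext] else x[which.max(abs(x))]
  lo <- min(cand); hi <- max(cand)
  tie <- isTRUE(all.equal(abs(lo), abs(hi))) && lo < 0
  out <- if (abs(lo) > abs(hi)) lo else hi
  if (tie) out <- abs(hi)
  attr(out, "tie") <- tie
  out
}

#' Depolarization peak-to-peak amplitude of one electrogram
#'
#' Maximum minus minimum of the waveform over the depolarization segment
#' (EGM onset to repolarization-window onset).
#'
#' @param phi Waveform; `t` sample times (ms).
#' @param segment `c(onset, tw_on)` in ms, or a [delineate()] result.
#' @return Non-negative amplitude.
#' @export
depol_amplitude <- function(phi, t, segment) {
  if (inherits(segment, "repol_window"))
    segment <- c(segment$onset, segment$tw_on)
  sel <- t >= segment[1] & t <= segment[2]
  if (!any(sel)) stop("empty depolarization segment")
  x <- phi[sel]
  max(x) - min(x)
}

#' Per-electrode amplitude maps
#'
#' Computes the signed repolarization amplitude and the depolarization
#' peak-to-peak amplitude of every electrode. Repolarization amplitudes may
#' be read from a differently filtered grid (`egm_repol`) than
#' depolarization amplitudes (`egm_depol`), as done for noisy signals.
#'
#' @param egm_repol `achmap_egm` used for repolarization analysis.
#' @param egm_depol `achmap_egm` for depolarization analysis (defaults to
#'   the same grid).
#' @param window Optional [delineate()] result (delineated from
#'   `egm_repol` when omitted).
#' @return Tibble (`row`, `col`, `R_A`, `D_A`) with attributes `R_A_max`,
#'   `D_A_max` (grid maxima) and `window`.
#' @export
amplitude_maps <- function(egm_repol, egm_depol = egm_repol, window = NULL) {
  if (is.null(window)) window <- delineate(egm_repol)
  t <- egm_repol$t
  R_A <- apply(egm_repol$phi, 2, function(x)
    as.numeric(repol_amplitude(x, t, window)))
  D_A <- apply(egm_depol$phi, 2, function(x)
    depol_amplitude(x, egm_depol$t, window))
  out <- tibble::tibble(row = egm_repol$grid$row, col = egm_repol$grid$col,
                        R_A = R_A, D_A = D_A)
  attr(out, "R_A_max") <- R_A[which.max(abs(R_A))]
  attr(out, "D_A_max") <- max(D_A)
  attr(out, "window") <- window
  out
}

#' ROC-optimal threshold over an explicit threshold grid
#'
#' Scans the supplied thresholds, computing sensitivity and specificity of
#' the rule `score > threshold` (`direction = "greater"`, ACh detection) or
#' `score < threshold` (`direction = "less"`, fibrosis detection), and
#' returns the threshold whose ROC point minimizes the Euclidean distance to
#' the (FPR 0, Se 1) corner. Ties resolve to the higher-sensitivity point,
#' then to the first threshold.
#'
#' @param scores Numeric scores, one per electrode.
#' @param truth Logical ground truth (positives).
#' @param thresholds Threshold grid to scan (e.g. [r_threshold_grid()]).
#' @param direction `"greater"` or `"less"`.
#' @return List: `threshold`, `se`, `sp`, `dist`, and `roc` (a tibble with
#'   one row per scanned threshold).
#' @export
roc_optimal_threshold <- function(scores, truth, thresholds,
                                  direction = c("greater", "less")) {
  direction <- match.arg(direction)
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) stop("scores/truth length mismatch")
  if (!any(truth) || all(truth))
    stop("both classes must be present in the ground truth")
  pos <- sum(truth); neg <- sum(!truth)
  roc <- tibble::tibble(threshold = sort(thresholds))
  pred <- if (direction == "greater")
    outer(scores, roc$threshold, `>`) else outer(scores, roc$threshold, `<`)
  roc$se <- colSums(pred & truth) / pos
  roc$sp <- colSums(!pred & !truth) / neg
  roc$fpr <- 1 - roc$sp
  roc$dist <- sqrt((1 - roc$se)^2 + roc$fpr^2)
  ord <- order(roc$dist, -roc$se)
  best <- ord[1]
  list(threshold = roc$threshold[best], se = roc$se[best], sp = roc$sp[best],
       dist = roc$dist[best], roc = roc)
}

#' Threshold grids for the ROC scans
#'
#' The depolarization grid holds 40 values in 0.1 mV steps centered at the
#' global mean amplitude; the repolarization grid holds values in steps of
#' 1% of the grid-maximum repolarization amplitude across a configurable
#' percentage span (default -80% to +80%, about 160 values; fibrotic-region
#' optima can be negative).
#'
#' @param d_a Depolarization amplitudes (mV).
#' @param step Grid step (mV).
#' @param n Number of grid values.
#' @return Numeric vector of thresholds.
#' @export
d_threshold_grid <- function(d_a, step = 0.1, n = 40) {
  mean(d_a) + (seq_len(n) - 1 - n %/% 2) * step
}

#' @rdname d_threshold_grid
#' @param r_a_max Grid-maximum repolarization amplitude (signed, Eq.-style
#'   maximum of the map).
#' @param span Percentage span `c(lo, hi)`.
#' @export
r_threshold_grid <- function(r_a_max, span = c(-80, 80)) {
  seq(span[1], span[2], by = 1) / 100 * r_a_max
}

#' Classify electrodes into ACh / fibrosis categories
#'
#' One-stage mode applies a single repolarization threshold (`R_A > r_th`
#' means ACh), used for tissues without fibrosis or with uniform diffuse
#' fibrosis. Two-stage mode first labels electrodes fibrotic when their
#' depolarization amplitude falls below `d_th`, then applies a
#' region-specific repolarization threshold.
#'
#' @param amps Amplitude map from [amplitude_maps()].
#' @param r_th Repolarization threshold (mV) for non-fibrotic electrodes.
#' @param d_th Depolarization threshold (mV); two-stage only.
#' @param r_th_fibro Repolarization threshold (mV) inside fibrotic areas
#'   (may be negative); two-stage only.
#' @param mode `"one_stage"` or `"two_stage"`.
#' @return `amps` extended with `pred_fibro`, `pred_ach` and a 4-level
#'   `label` factor.
#' @export
classify_electrodes <- function(amps, r_th, d_th = NULL, r_th_fibro = NULL,
                                mode = c("one_stage", "two_stage")) {
  mode <- match.arg(mode)
  if (mode == "two_stage") {
    if (is.null(d_th) || is.null(r_th_fibro))
      stop("two-stage classification needs d_th and r_th_fibro")
    fibro <- amps$D_A < d_th
    ach <- ifelse(fibro, amps$R_A > r_th_fibro, amps$R_A > r_th)
  } else {
    fibro <- rep(FALSE, nrow(amps))
    ach <- amps$R_A > r_th
  }
  amps$pred_fibro <- fibro
  amps$pred_ach <- ach
  amps$label <- factor(dplyr::case_when(
    ach & fibro ~ "ACh+fibro",
    ach ~ "ACh",
    fibro ~ "nonACh+fibro",
    TRUE ~ "nonACh"),
    levels = c("nonACh", "ACh", "nonACh+fibro", "ACh+fibro"))
  amps
}

#' Ground-truth electrode labels from the tissue geometry
#'
#' An electrode is ACh-positive when its center lies inside (boundary
#' inclusive) an acetylcholine circle of the registry, and fibrotic when it
#' lies inside a fibrosis patch.
#'
#' @param grid [electrode_grid()].
#' @param tissue [tissue_model()] or any list carrying a `registry` tibble.
#' @return Tibble `row`, `col`, `truth_ach`, `truth_fibro`.
#' @export
ground_truth <- function(grid, tissue) {
  reg <- tissue$registry
  hit <- function(kind) {
    circles <- reg[reg$kind == kind, , drop = FALSE]
    if (nrow(circles) == 0) return(rep(FALSE, nrow(grid)))
    Reduce(`|`, lapply(seq_len(nrow(circles)), function(k)
      sqrt((grid$x - circles$x[k])^2 + (grid$y - circles$y[k])^2) <=
        circles$r[k]))
  }
  tibble::tibble(row = grid$row, col = grid$col,
                 truth_ach = hit("ACh"), truth_fibro = hit("fibrosis"))
}

#' Detection performance metrics
#'
#' Accuracy, sensitivity and false positive rate (1 - specificity) of the
#' per-electrode ACh classification.
#'
#' @param pred,truth Logical vectors (positives = ACh).
#' @return List `ac`, `se`, `fpr`.
#' @export
detection_metrics <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("shape mismatch")
  if (length(pred) == 0) stop("empty prediction")
  pred <- as.logical(pred); truth <- as.logical(truth)
  tp <- sum(pred & truth); tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  list(ac = (tp + tn) / length(pred),
       se = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_)
}

#' Full acetylcholine-site detection on an electrogram grid
#'
#' Runs the complete post-processing chain: repolarization-window
#' delineation, amplitude maps, ROC-optimal thresholds against the
#' tissue-derived ground truth (or user-supplied thresholds), one- or
#' two-stage classification, and metrics.
#'
#' In two-stage mode the fibrosis threshold is optimized first on the
#' depolarization amplitudes; repolarization thresholds are then optimized
#' separately within the predicted non-fibrotic and fibrotic regions. A
#' region whose ground truth is single-class falls back to the other
#' region's percentage threshold (recorded in `fallbacks`).
#'
#' @param egm_repol `achmap_egm` for repolarization analysis.
#' @param tissue Tissue (or phantom) carrying the ground-truth registry.
#' @param egm_depol Optional differently filtered grid for depolarization.
#' @param mode `"auto"` (two-stage iff fibrosis patches are registered),
#'   `"one_stage"` or `"two_stage"`.
#' @param span Percentage span of the repolarization threshold grid.
#' @param thresholds Optional fixed thresholds (skips the ROC): list with
#'   `r_th_pct`, and for two-stage `d_th_pct`, `r_th_fibro_pct`, interpreted
#'   as percentages of the grid maxima.
#' @return Object of class `achmap_detection`.
#' @export
detect_ach <- function(egm_repol, tissue, egm_depol = egm_repol,
                       mode = c("auto", "one_stage", "two_stage"),
                       span = c(-80, 80), thresholds = NULL) {
  mode <- match.arg(mode)
  amps <- amplitude_maps(egm_repol, egm_depol)
  truth <- ground_truth(egm_repol$grid, tissue)
  amps <- dplyr::left_join(amps, truth, by = c("row", "col"))
  r_max <- attr(amps, "R_A_max"); d_max <- attr(amps, "D_A_max")
  if (mode == "auto") {
    mode <- if (any(truth$truth_fibro)) "two_stage" else "one_stage"
  }
  fallbacks <- character(0)
  if (!is.null(thresholds)) {
    r_th <- thresholds$r_th_pct / 100 * r_max
    d_th <- if (!is.null(thresholds$d_th_pct))
      thresholds$d_th_pct / 100 * d_max else NULL
    r_th_fibro <- if (!is.null(thresholds$r_th_fibro_pct))
      thresholds$r_th_fibro_pct / 100 * r_max else NULL
    rocs <- NULL
  } else if (mode == "one_stage") {
    opt <- roc_optimal_threshold(amps$R_A, amps$truth_ach,
                                 r_threshold_grid(r_max, span), "greater")
    r_th <- opt$threshold; d_th <- NULL; r_th_fibro <- NULL
    rocs <- list(r = opt)
  } else {
    opt_d <- roc_optimal_threshold(amps$D_A, amps$truth_fibro,
                                   d_threshold_grid(amps$D_A), "less")
    d_th <- opt_d$threshold
    pred_fibro <- amps$D_A < d_th
    grid_r <- r_threshold_grid(r_max, span)
    opt_region <- function(sel, label) {
      tr <- amps$truth_ach[sel]
      if (sum(sel) == 0 || !any(tr) || all(tr)) {
        fallbacks <<- c(fallbacks, label)
        return(NULL)
      }
      roc_optimal_threshold(amps$R_A[sel], tr, grid_r, "greater")
    }
    opt_n <- opt_region(!pred_fibro, "non_fibrotic")
    opt_f <- opt_region(pred_fibro, "fibrotic")
    if (is.null(opt_n) && is.null(opt_f))
      stop("no region with both ACh classes present; cannot optimize thresholds")
    r_th <- if (!is.null(opt_n)) opt_n$threshold else opt_f$threshold
    r_th_fibro <- if (!is.null(opt_f)) opt_f$threshold else r_th
    rocs <- list(d = opt_d, r = opt_n, r_fibro = opt_f)
  }
  cls <- classify_electrodes(amps, r_th = r_th, d_th = d_th,
                             r_th_fibro = r_th_fibro, mode = mode)
  met <- detection_metrics(cls$pred_ach, cls$truth_ach)
  structure(list(map = cls, mode = mode,
                 thresholds = list(
                   r_th = r_th, d_th = d_th, r_th_fibro = r_th_fibro,
                   r_th_pct = 100 * r_th / r_max,
                   d_th_pct = if (!is.null(d_th)) 100 * d_th / d_max else NA_real_,
                   r_th_fibro_pct = if (!is.null(r_th_fibro))
                     100 * r_th_fibro / r_max else NA_real_,
                   R_A_max = r_max, D_A_max = d_max),
                 window = attr(amps, "window"), rocs = rocs,
                 metrics = met, fallbacks = fallbacks),
            class = "achmap_detection")
}

#' @export
print.achmap_detection <- function(x, ...) {
  cat(sprintf("<achmap_detection %s: Ac %.3f, Se %.3f, FPR %.3f; R_th %.1f%% of R_A_max>\n",
              x$mode, x$metrics$ac, x$metrics$se, x$metrics$fpr,
              x$thresholds$r_th_pct))
  invisible(x)
}

#' @export
tidy.achmap_detection <- function(x, ...) x$map

#' @export
glance.achmap_detection <- function(x, ...) {
  tibble::tibble(mode = x$mode, ac = x$metrics$ac, se = x$metrics$se,
                 fpr = x$metrics$fpr, r_th_pct = x$thresholds$r_th_pct,
                 d_th_pct = x$thresholds$d_th_pct,
                 r_th_fibro_pct = x$thresholds$r_th_fibro_pct,
                 R_A_max = x$thresholds$R_A_max,
                 D_A_max = x$thresholds$D_A_max,
                 n_fallbacks = length(x$fallbacks))
}
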