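# Polysome-profile processing and qPCR analytics (tRNA charging, ddCt).

moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  n <- length(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + (window - 1L - half))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Process a raw polysome absorbance profile
#'
#' Smooths the A254 trace with a centred moving average (edges truncated),
#' shifts the baseline so the overall minimum is zero, piecewise-linearly
#' reparameterises the position axis so every anchor lands exactly on its
#' reference position (run-to-run alignment), and normalises the trace to
#' unit total area under the curve (trapezoid rule).
#'
#' @param position,absorbance Numeric vectors of the raw trace.
#' @param anchors Strictly increasing anchor positions in the raw frame
#'   (monosome/polysome peaks, local extrema).
#' @param ref_anchors Matching reference positions (same length).
#' @param smooth_window Moving-average width in points (default 5).
#' @return A `polysome_profile`: list with `position` (aligned),
#'   `absorbance` (smoothed, baselined, AUC-normalised), `anchors`
#'   (aligned, equal to `ref_anchors`), and `auc_raw`.
#' @export
process_polysome_profile <- function(position, absorbance, anchors, ref_anchors,
                                     smooth_window = 5L) {
  stopifnot(length(position) == length(absorbance))
  if (length(anchors) < 2L || length(anchors) != length(ref_anchors))
    stop("need >= 2 matched anchor pairs")
  if (any(diff(anchors) <= 0) || any(diff(ref_anchors) <= 0))
    stop("anchors must be strictly increasing")
  if (min(anchors) < min(position) || max(anchors) > max(position))
    stop("anchors outside the trace range")
  y <- moving_average(absorbance, smooth_window)
  y <- y - min(y)
  # map each raw position through the piecewise-linear anchor correspondence,
  # extending the terminal segments beyond the outer anchors
  xa <- c(-Inf, anchors, Inf)
  seg <- findInterval(position, anchors, all.inside = TRUE)
  slope <- diff(ref_anchors) / diff(anchors)
  newx <- ref_anchors[seg] + (position - anchors[seg]) * slope[seg]
  auc <- trapz(newx, y)
  if (auc <= 0) stop("degenerate profile: zero area under the curve after baselining")
  structure(list(position = newx, absorbance = y / auc,
                 anchors = ref_anchors, auc_raw = auc),
            class = "polysome_profile")
}

#' Polysome-to-monosome ratio from a processed profile
#'
#' Trapezoidal AUC over the monosome and polysome windows (disjoint,
#' boundaries interpolated onto the aligned axis), ratio
#' polysome/monosome, optionally normalised to a control ratio.
#'
#' @param profile A `polysome_profile`.
#' @param monosome_window,polysome_window Length-2 numeric ranges on the
#'   aligned position axis.
#' @param control_ratio Optional control P/M ratio to normalise against.
#' @return List: monosome_auc, polysome_auc, pm_ratio, pm_ratio_normalized.
#' @export
pm_ratio <- function(profile, monosome_window, polysome_window,
                     control_ratio = NULL) {
  if (max(monosome_window[1], polysome_window[1]) <
      min(monosome_window[2], polysome_window[2]))
    stop("monosome and polysome windows must be disjoint")
  window_auc <- function(win) {
    x <- profile$position
    inside <- x >= win[1] & x <= win[2]
    xs <- c(win[1], x[inside], win[2])
    ys <- approx(x, profile$absorbance, xout = xs, rule = 2)$y
    o <- order(xs)
    trapz(xs[o], ys[o])
  }
  m <- window_auc(monosome_window)
  p <- window_auc(polysome_window)
  if (m <= 0) stop("zero monosome AUC")
  ratio <- p / m
  list(monosome_auc = m, polysome_auc = p, pm_ratio = ratio,
       pm_ratio_normalized = if (is.null(control_ratio)) NA_real_ else ratio / control_ratio)
}

#' Spike-normalised relative tRNA charging from Ct values
#'
#' Per sample, dCt = Ct(target) - Ct(spike); per isoacceptor, ddCt of each
#' starved replicate against the mean control dCt and relative charging
#' 2^(-ddCt), with a one-sample t-test of the replicate log2 ratios against
#' 0.
#'
#' @param measurements data.frame: sample_id, condition, isoacceptor,
#'   ct_target, ct_spike. Rows with missing spike Ct are dropped with a
#'   warning.
#' @param control Control condition label (default "Ctrl").
#' @param alpha Significance threshold (default 0.05).
#' @return data.table: isoacceptor, relative_charging (geometric mean over
#'   replicates), sem_log2, p, significant.
#' @export
trna_charging_relative <- function(measurements, control = "Ctrl", alpha = 0.05) {
  m <- as.data.table(measurements)
  drop <- is.na(m$ct_spike) | is.na(m$ct_target)
  if (any(drop)) {
    warning(sprintf("dropping %d measurement(s) with missing Ct", sum(drop)))
    m <- m[!drop]
  }
  m[, dct := ct_target - ct_spike]
  ctrl <- m[condition == control, .(dct_ctrl = mean(dct)), by = "isoacceptor"]
  starved <- m[condition != control][ctrl, on = "isoacceptor", nomatch = NULL]
  starved[, log2_ratio := -(dct - dct_ctrl)]   # log2 relative charging
  starved[, .(relative_charging = 2^mean(log2_ratio),
              sem_log2 = sd(log2_ratio) / sqrt(.N),
              p = if (.N >= 2 && sd(log2_ratio) > 0) t.test(log2_ratio)$p.value
                  else as.numeric(mean(log2_ratio) == 0),
              n = .N), by = "isoacceptor"][, significant := p < alpha][]
}

#' Gene-expression fold change by the delta-delta-Ct method
#'
#' Normalises each target Ct to the housekeeping gene in the same sample
#' (dCt), references the mean control dCt (ddCt), and reports fold change
#' 2^(-ddCt) with mean and SEM per condition. Samples without a
#' housekeeping Ct are dropped.
#'
#' @param ct_table data.frame: sample_id, condition, target, ct. Must
#'   contain the housekeeping gene as one of the targets.
#' @param target Target gene name.
#' @param housekeeping Housekeeping gene name (e.g. "Gapdh").
#' @param control Control condition label.
#' @return List with `samples` (per-sample fold changes) and `summary`
#'   (per condition: mean_fc, sem, n).
#' @export
ddct_fold_change <- function(ct_table, target, housekeeping, control = "Ctrl") {
  ct <- as.data.table(ct_table)
  hk_name <- housekeeping
  tgt_name <- target
  hk <- ct[target == hk_name, .(sample_id, ct_hk = ct)]
  tg <- ct[target == tgt_name, .(sample_id, condition, ct)]
  miss <- setdiff(tg$sample_id, hk$sample_id)
  if (length(miss))
    warning("dropping sample(s) without housekeeping Ct: ", paste(miss, collapse = ", "))
  tg <- tg[hk, on = "sample_id", nomatch = NULL]
  tg[, dct := ct - ct_hk]
  ctrl_mean <- tg[condition == control, mean(dct)]
  if (!is.finite(ctrl_mean)) stop("no control samples for ddCt reference")
  tg[, fold_change := 2^(-(dct - ctrl_mean))]
  summary <- tg[, .(mean_fc = mean(fold_change),
                    sem = sd(fold_change) / sqrt(.N), n = .N), by = "condition"]
  list(samples = tg[, c("sample_id", "condition", "dct", "fold_change")],
       summary = summary)
}
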