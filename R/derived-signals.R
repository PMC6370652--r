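#' Instantaneous heart rate on a target grid
#'
#' Converts R-peak times to interval rates (60/RR, beats/min) placed at
#' interval midpoints and interpolates piecewise-linearly onto the target
#' grid, with constant extrapolation beyond the first/last midpoint. Values
#' are therefore always bounded by the extreme observed interval rates.
#'
#' @param r_peaks \code{rpeak_series} or numeric vector of peak times (s).
#' @param target_times numeric vector of output sample times (s).
#' @param units "rate" for beats/min, "interval" for seconds.
#' @return numeric series on the target grid.
#' @export
compute_ihr <- function(r_peaks, target_times, units = c("rate", "interval")) {
  units <- match.arg(units)
  times <- as.numeric(r_peaks)
  if (length(times) < 3L) stop("need at least 3 R peaks", call. = FALSE)
  iv <- diff(times)
  mid <- times[-length(times)] + iv / 2
  val <- if (units == "rate") 60 / iv else iv
  approx(mid, val, xout = target_times, rule = 2)$y
}

#' Instantaneous respiratory rate on a target grid
#'
#' As \code{\link{compute_ihr}}, for inspiratory-onset intervals
#' (breaths/min by default).
#'
#' @param insp_onsets numeric vector of inspiratory onset times (s).
#' @inheritParams compute_ihr
#' @return numeric series on the target grid.
#' @export
compute_irr <- function(insp_onsets, target_times, units = c("rate", "interval")) {
  units <- match.arg(units)
  if (length(insp_onsets) < 3L) stop("need at least 3 inspiratory onsets", call. = FALSE)
  compute_ihr(as.numeric(insp_onsets), target_times, units = units)
}

#' Anti-aliased integer-factor downsampling
#'
#' Zero-phase Butterworth low-pass (order 4, cutoff 0.4 * fs_out) followed
#' by decimation. Passband gain is unity within 1%; content above the
#' output Nyquist is suppressed below 1%.
#'
#' @param x numeric series.
#' @param fs_in,fs_out input/output sampling rates; the ratio must be an
#'   integer.
#' @return decimated series (every \code{fs_in/fs_out}-th sample).
#' @export
downsample <- function(x, fs_in, fs_out) {
  fac <- fs_in / fs_out
  if (abs(fac - round(fac)) > 1e-8 || fac < 1) {
    stop("fs_in/fs_out must be a positive integer factor", call. = FALSE)
  }
  fac <- as.integer(round(fac))
  if (fac == 1L) return(x)
  lp <- signal::butter(4, (0.4 * fs_out) / (fs_in / 2), type = "low")
  mu <- mean(x)
  xf <- signal::filtfilt(lp, x - mu) + mu   # filter around DC: exact unity gain
  xf[seq(1L, length(x), by = fac)]
}

#' Build the co-sampled TV / iRR / iHR signal set
#'
#' Runs the preprocessing chain on a raw recording (ECG detrend + R-peak
#' detection, impedance smoothing + breath-phase annotation) and assembles
#' the tidal-volume, instantaneous-respiratory-rate and
#' instantaneous-heart-rate series at the requested rate (25 Hz; pass
#' \code{fs_out = 2.5} or use \code{\link{downsample_signal_set}} for the
#' spectral representation).
#'
#' @param rec a \code{raw_recording}.
#' @param fs_out output rate in Hz.
#' @param tau_frac dead-band fraction for \code{\link{detect_breath_phases}}.
#' @return object of class \code{signal_set}: list with \code{fs},
#'   \code{t}, \code{series} (matrix with columns \code{tv}, \code{irr},
#'   \code{ihr}) plus the intermediate \code{r_peaks}, \code{z_smooth},
#'   \code{phases}, \code{insp_onsets}.
#' @export
build_signal_set <- function(rec, fs_out = 25, tau_frac = 0.05) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$fs
  ecg_d <- detrend_ecg(rec$ecg, fs)
  r_peaks <- detect_r_peaks(ecg_d, fs)
  if (length(r_peaks) < 3L) stop("too few R peaks detected", call. = FALSE)
  z_s <- smooth_impedance(rec$impedance, fs)
  phases <- detect_breath_phases(z_s, fs, tau_frac = tau_frac)
  onsets <- inspiratory_onsets(phases, fs)
  if (length(onsets) < 3L) stop("too few inspiratory onsets detected", call. = FALSE)

  tv <- downsample(z_s, fs, fs_out)
  t_out <- (seq_along(tv) - 1L) / fs_out
  irr <- compute_irr(onsets, t_out)
  ihr <- compute_ihr(r_peaks, t_out)
  series <- cbind(tv = tv, irr = irr, ihr = ihr)
  structure(list(fs = fs_out, t = t_out, series = series,
                 r_peaks = r_peaks, z_smooth = z_s, phases = phases,
                 insp_onsets = onsets, subject_id = rec$subject_id,
                 posture = rec$posture),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("signal set at %g Hz: %d samples of tv/irr/ihr (%s, %s)\n",
              x$fs, nrow(x$series), x$subject_id %||% "?", x$posture %||% "?"))
  invisible(x)
}

#' Downsample a signal set by an integer factor
#'
#' @param ss a \code{signal_set}.
#' @param fs_out new rate (default 2.5 Hz, the spectral-analysis rate).
#' @return a new \code{signal_set} at \code{fs_out}.
#' @export
downsample_signal_set <- function(ss, fs_out = 2.5) {
  stopifnot(inherits(ss, "signal_set"))
  series <- apply(ss$series, 2, downsample, fs_in = ss$fs, fs_out = fs_out)
  out <- ss
  out$fs <- fs_out
  out$series <- series
  out$t <- (seq_len(nrow(series)) - 1L) / fs_out
  out
}

#' Beat-by-beat sequence at the detected R peaks
#'
#' Per-R-peak vectors: lengths of consecutive RR intervals, tidal-volume
#' related impedance amplitude at the peak, instantaneous respiratory rate
#' at the peak, and the breathing-phase code \{+1, -1, 0\} at the peak.
#' \code{rr[i]} spans peaks i to i+1; there are therefore
#' \code{length(r_peaks) - 1} RR values and one per-peak covariate sample
#' per peak.
#'
#' @param r_peaks \code{rpeak_series} or numeric peak times (s).
#' @param z_smooth smoothed impedance series.
#' @param phases \code{breath_phase_series} aligned to \code{z_smooth}.
#' @param insp_onsets inspiratory onset times (s).
#' @param fs sampling rate of \code{z_smooth}/\code{phases} in Hz.
#' @return object of class \code{beat_sequence}: list with \code{t_rpeak},
#'   \code{rr}, \code{amp}, \code{irr_at_r}, \code{phase_at_r}.
#' @export
build_beat_sequence <- function(r_peaks, z_smooth, phases, insp_onsets, fs) {
  times <- as.numeric(r_peaks)
  if (length(times) < 3L) stop("need at least 3 R peaks", call. = FALSE)
  n_z <- length(z_smooth)
  if (max(times) > n_z / fs || min(times) < 0) {
    stop("R-peak times fall outside the impedance recording", call. = FALSE)
  }
  rr <- diff(times)
  if (any(rr <= 0.2)) stop("RR intervals at or below the 0.2 s refractory guard",
                           call. = FALSE)
  idx <- pmin(n_z, pmax(1L, as.integer(round(times * fs)) + 1L))
  amp <- approx(seq_len(n_z) / fs - 1 / fs, z_smooth, xout = times, rule = 2)$y
  irr_at_r <- compute_irr(insp_onsets, times)
  phase_at_r <- as.integer(phases)[idx]
  structure(list(t_rpeak = times, rr = rr, amp = amp,
                 irr_at_r = irr_at_r, phase_at_r = phase_at_r),
            class = "beat_sequence")
}

#' @export
print.beat_sequence <- function(x, ...) {
  cat(sprintf("beat sequence: %d R peaks, mean RR %.0f ms, phase codes %s\n",
              length(x$t_rpeak), mean(x$rr) * 1000,
              paste(sort(unique(x$phase_at_r)), collapse = "/")))
  invisible(x)
}

# Aligned regression matrix for beat-domain models: rr[i] spans peaks
# i -> i+1; per-peak covariates are taken at peak i+1 (cause precedes
# effect), dropping the first per-peak sample.
beat_matrix <- function(seq) {
  stopifnot(inherits(seq, "beat_sequence"))
  n <- length(seq$rr)
  cbind(rr = seq$rr,
        amp = seq$amp[-1L][seq_len(n)],
        irr_at_r = seq$irr_at_r[-1L][seq_len(n)],
        phase_at_r = as.numeric(seq$phase_at_r[-1L][seq_len(n)]))
}

#' Augmented Dickey-Fuller stationarity screen
#'
#' Unit-root test with a constant (optionally a linear trend) in the test
#' regression and automatic augmentation-lag choice
#' (\code{trunc((n - 1)^(1/3))} by default). The p-value interpolates the
#' standard Dickey-Fuller critical-value table for the chosen
#' deterministic-terms variant. Following the screening convention used
#' here, the series is flagged stationary when p < 0.05 (the null is a
#' unit root).
#'
#' @param x numeric series, length >= 50, non-constant.
#' @param type deterministic terms: "constant" (default) or "trend".
#' @param k augmentation lag order; default \code{trunc((n-1)^(1/3))}.
#' @param alpha stationarity call threshold.
#' @param series_name label carried into the report.
#' @return object of class \code{stationarity_report}: list with
#'   \code{series_name}, \code{statistic}, \code{p_value},
#'   \code{stationary}, \code{lag_order}, \code{type}.
#' @examples
#' set.seed(1)
#' adf_stationarity(rnorm(500))$stationary          # TRUE
#' adf_stationarity(cumsum(rnorm(500)))$stationary  # FALSE
#' @export
adf_stationarity <- function(x, type = c("constant", "trend"), k = NULL,
                             alpha = 0.05, series_name = deparse(substitute(x))) {
  type <- match.arg(type)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 50L) stop("series too short for the ADF screen (need >= 50)", call. = FALSE)
  if (sd(x) == 0) stop("constant series has no unit-root structure", call. = FALSE)
  k <- k %||% trunc((n - 1)^(1 / 3))
  k <- max(0L, as.integer(k))

  dx <- diff(x)
  m <- length(dx) - k
  y <- dx[(k + 1L):length(dx)]
  X <- cbind(const = 1, ylag = x[(k + 1L):(n - 1L)])
  if (k > 0L) {
    aug <- sapply(seq_len(k), function(j) dx[(k + 1L - j):(length(dx) - j)])
    X <- cbind(X, aug)
  }
  if (type == "trend") X <- cbind(X, trend = seq_len(m))
  fit <- qr(X)
  beta <- qr.coef(fit, y)
  res <- qr.resid(fit, y)
  s2 <- sum(res^2) / (m - ncol(X))
  XtX_inv <- chol2inv(qr.R(fit))
  se <- sqrt(s2 * XtX_inv[2L, 2L])
  stat <- beta[["ylag"]] / se
  p <- adf_pvalue(stat, m, type)
  structure(list(series_name = series_name, statistic = stat, p_value = p,
                 stationary = p < alpha, lag_order = k, type = type),
            class = "stationarity_report")
}

#' @export
print.stationarity_report <- function(x, ...) {
  cat(sprintf("ADF (%s, %d lags) on %s: tau = %.3f, p %s %.3g -> %s\n",
              x$type, x$lag_order, x$series_name, x$statistic,
              if (attr(x$p_value, "bounded") %||% FALSE) "~" else "=",
              x$p_value, if (x$stationary) "stationary" else "non-stationary"))
  invisible(x)
}

# Dickey-Fuller tau critical values (constant / constant+trend variants),
# interpolated in both sample size and statistic, tseries-style.
adf_pvalue <- function(stat, n, type) {
  probs <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
  sizes <- c(25, 50, 100, 250, 500, 1e5)
  tab <- if (type == "constant") {
    rbind(c(-3.75, -3.33, -3.00, -2.62, -0.37, 0.00, 0.34, 0.72),
          c(-3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66),
          c(-3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63),
          c(-3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62),
          c(-3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61),
          c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60))
  } else {
    rbind(c(-4.38, -3.95, -3.60, -3.24, -1.14, -0.80, -0.50, -0.15),
          c(-4.15, -3.80, -3.50, -3.18, -1.19, -0.87, -0.58, -0.24),
          c(-4.04, -3.73, -3.45, -3.15, -1.22, -0.90, -0.62, -0.28),
          c(-3.99, -3.69, -3.43, -3.13, -1.23, -0.92, -0.64, -0.31),
          c(-3.98, -3.68, -3.42, -3.13, -1.24, -0.93, -0.65, -0.32),
          c(-3.96, -3.66, -3.41, -3.12, -1.25, -0.94, -0.66, -0.33))
  }
  crit <- vapply(seq_along(probs), function(j) {
    approx(sizes, tab[, j], xout = min(n, 1e5), rule = 2)$y
  }, numeric(1))
  bounded <- stat < crit[1L] || stat > crit[length(crit)]
  p <- approx(crit, probs, xout = stat, rule = 2)$y
  attr(p, "bounded") <- bounded
  p
}

#' Stationarity screen of a signal set
#'
#' @param ss a \code{signal_set}.
#' @param ... passed to \code{\link{adf_stationarity}}.
#' @return data frame with one row per channel: \code{series_name},
#'   \code{statistic}, \code{p_value}, \code{stationary}.
#' @export
screen_stationarity <- function(ss, ...) {
  stopifnot(inherits(ss, "signal_set"))
  rows <- lapply(colnames(ss$series), function(ch) {
    r <- adf_stationarity(ss$series[, ch], series_name = ch, ...)
    data.frame(series_name = ch, statistic = r$statistic,
               p_value = as.numeric(r$p_value), stationary = r$stationary,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
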