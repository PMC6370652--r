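#' Remove baseline wander from an ECG channel
#'
#' Two-stage median-filter baseline estimation (200 ms then 600 ms windows)
#' subtracted from the signal. The 600 ms second stage tracks drift well
#' below the QRS time scale, so sub-0.5 Hz wander is strongly attenuated
#' while QRS morphology is preserved.
#'
#' @param ecg numeric ECG series (arbitrary amplitude units).
#' @param fs sampling rate in Hz.
#' @return detrended series of the same length.
#' @export
detrend_ecg <- function(ecg, fs) {
  if (length(ecg) < fs) stop("ECG shorter than 1 s; cannot detrend", call. = FALSE)
  k1 <- odd_window(0.2 * fs)
  k2 <- odd_window(0.6 * fs)
  baseline <- stats::runmed(ecg, k1, endrule = "median")
  baseline <- stats::runmed(baseline, k2, endrule = "median")
  as.numeric(ecg - baseline)
}

odd_window <- function(w) {
  w <- max(3L, as.integer(round(w)))
  if (w %% 2L == 0L) w + 1L else w
}

#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Band-pass (5--15 Hz), differentiate, square, integrate over a 150 ms
#' moving window, then threshold with adaptive signal/noise levels and a
#' 200 ms refractory period. Candidate fiducial points are refined to the
#' local maximum of the (detrended) ECG within +/- 50 ms.
#'
#' @param ecg detrended ECG series.
#' @param fs sampling rate in Hz (>= 200 for reliable QRS morphology).
#' @param refractory minimum peak spacing in seconds.
#' @return object of class \code{rpeak_series}: numeric vector of strictly
#'   increasing peak times in seconds from the start of the recording
#'   (empty when no peaks are found).
#' @export
detect_r_peaks <- function(ecg, fs, refractory = 0.2) {
  if (fs < 200) stop("sampling rate below 200 Hz is not supported", call. = FALSE)
  n <- length(ecg)
  if (n < fs) stop("ECG shorter than 1 s", call. = FALSE)
  if (all(ecg == ecg[1L])) return(new_rpeak_series(numeric(0)))

  bp <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bp, ecg)
  deriv <- c(0, diff(filt)) * fs
  sq <- deriv^2
  integ <- moving_average_reflect(sq, max(1L, as.integer(round(0.150 * fs))))

  refr <- as.integer(round(refractory * fs))
  # initial thresholds from the first 2 s
  init <- integ[seq_len(min(n, 2L * as.integer(fs)))]
  spki <- max(init) * 0.6
  npki <- mean(init) * 0.5
  thr <- npki + 0.25 * (spki - npki)

  peaks <- integer(0)
  last <- -refr
  i <- 2L
  while (i < n) {
    if (integ[i] >= integ[i - 1L] && integ[i] >= integ[i + 1L]) {
      if (integ[i] > thr && (i - last) > refr) {
        peaks <- c(peaks, i)
        last <- i
        spki <- 0.125 * integ[i] + 0.875 * spki
      } else {
        npki <- 0.125 * integ[i] + 0.875 * npki
      }
      thr <- npki + 0.25 * (spki - npki)
    }
    i <- i + 1L
  }
  if (!length(peaks)) return(new_rpeak_series(numeric(0)))

  # refine to local ECG maximum within +/- 50 ms
  half <- as.integer(round(0.05 * fs))
  ref <- vapply(peaks, function(p) {
    lo <- max(1L, p - half)
    hi <- min(n, p + half)
    lo + which.max(ecg[lo:hi]) - 1L
  }, integer(1))
  ref <- sort(unique(ref))
  # enforce refractory after refinement: keep the larger of close pairs
  keep <- rep(TRUE, length(ref))
  j <- 1L
  for (i in seq_along(ref)[-1L]) {
    if (ref[i] - ref[j] <= refr) {
      if (ecg[ref[i]] > ecg[ref[j]]) { keep[j] <- FALSE; j <- i } else keep[i] <- FALSE
    } else j <- i
  }
  new_rpeak_series((ref[keep] - 1L) / fs)
}

new_rpeak_series <- function(times) {
  structure(as.numeric(times), class = "rpeak_series")
}

#' @export
print.rpeak_series <- function(x, ...) {
  cat(sprintf("R-peak series: %d peaks", length(x)))
  if (length(x) > 1L) {
    cat(sprintf(", mean RR %.0f ms", mean(diff(unclass(x))) * 1000))
  }
  cat("\n")
  invisible(x)
}

#' Smooth a thoracic impedance channel
#'
#' Moving average over a 1 s window (reflect padding, output length equals
#' input length). The smoothed impedance stands in for the tidal-volume
#' signal; no impedance-to-volume calibration is applied.
#'
#' @param z impedance series (Ohm, uncalibrated).
#' @param fs sampling rate in Hz.
#' @param window averaging window in seconds.
#' @return smoothed series, same length as \code{z}.
#' @export
smooth_impedance <- function(z, fs, window = 1) {
  if (length(z) <= fs) stop("impedance series must exceed one window", call. = FALSE)
  moving_average_reflect(as.numeric(z), as.integer(round(window * fs)))
}

#' Annotate inspiration, expiration and pauses on an impedance signal
#'
#' Differentiates the smoothed (flow-related) impedance and codes each
#' sample +1 where the derivative exceeds +tau (inspiration), -1 below -tau
#' (expiration) and 0 inside the dead band (respiratory pause). The default
#' dead band is 5\% of the robust (10th--90th percentile) derivative range.
#'
#' @param z_smooth smoothed impedance series.
#' @param fs sampling rate in Hz.
#' @param tau dead-band half-width in derivative units; \code{NULL} for the
#'   robust default.
#' @param tau_frac fraction of the interdecile derivative range used when
#'   \code{tau} is \code{NULL}.
#' @param deriv_span half-span of the symmetric difference used for the
#'   derivative, in seconds; widening it low-passes the flow estimate well
#'   above breathing frequencies.
#' @return object of class \code{breath_phase_series}: integer vector in
#'   \{+1, -1, 0\} aligned to the input samples.
#' @export
detect_breath_phases <- function(z_smooth, fs, tau = NULL, tau_frac = 0.05,
                                 deriv_span = 0.1) {
  n <- length(z_smooth)
  if (n < 3L) stop("impedance series too short", call. = FALSE)
  d <- central_derivative(z_smooth, fs,
                          half_span = max(1L, as.integer(round(deriv_span * fs))))
  if (is.null(tau)) {
    qr <- quantile(d, c(0.1, 0.9), names = FALSE)
    tau <- tau_frac * (qr[2L] - qr[1L])
  }
  phase <- integer(n)
  phase[d > tau] <- 1L
  phase[d < -tau] <- -1L
  structure(phase, tau = tau, class = "breath_phase_series")
}

central_derivative <- function(x, fs, half_span = 1L) {
  n <- length(x)
  h <- min(half_span, n - 1L)
  fwd <- x[pmin(n, seq_len(n) + h)]
  bwd <- x[pmax(1L, seq_len(n) - h)]
  span <- (pmin(n, seq_len(n) + h) - pmax(1L, seq_len(n) - h)) / fs
  (fwd - bwd) / span
}

#' Inspiratory onset times from a breath-phase series
#'
#' The onset of each breath is taken as the first sample of every maximal
#' run of +1 (inspiration) codes.
#'
#' @param phases \code{breath_phase_series} (or integer vector in
#'   \{+1, -1, 0\}).
#' @param fs sampling rate in Hz.
#' @param min_sep minimum separation between successive onsets in seconds;
#'   closer candidates (threshold chatter around the dead band) are
#'   dropped. The 1 s default matches the upper physiological breathing
#'   rate handled here.
#' @return numeric vector of onset times in seconds.
#' @export
inspiratory_onsets <- function(phases, fs, min_sep = 1.0) {
  ph <- as.integer(phases)
  starts <- which(ph == 1L & c(0L, head(ph, -1L)) != 1L)
  times <- (starts - 1L) / fs
  if (length(times) > 1L && min_sep > 0) {
    keep <- c(TRUE, diff(times) >= min_sep)
    while (!all(keep)) {
      times <- times[keep]
      keep <- c(TRUE, diff(times) >= min_sep)
    }
  }
  times
}
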