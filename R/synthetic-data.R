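#' Specification of a synthetic cardiorespiratory recording
#'
#' Parameter set for one simulated posture session. Postures carry presets
#' (supine: mean heart rate 60 bpm, breathing 0.23 Hz; standing: 75 bpm,
#' 0.19 Hz) which individual arguments override. Respiration is a phase
#' oscillator with jittered cycle lengths (coefficient of variation ~10%),
#' so the instantaneous respiratory rate is non-degenerate; heart rate is
#' modulated by the breathing waveform (respiratory sinus arrhythmia) with
#' a configurable time lead of the heart-rate maximum over the tidal-volume
#' maximum.
#'
#' @param posture "supine" or "standing".
#' @param mean_hr mean heart rate, beats/min.
#' @param resp_rate mean breathing rate, Hz.
#' @param rsa_gain fractional heart-rate modulation depth (>= 0).
#' @param phase_lead seconds by which the heart-rate maximum precedes the
#'   tidal-volume maximum (positive = cardiac leads).
#' @param duration recording length in seconds (>= 60).
#' @param fs sampling rate in Hz.
#' @param noise_sd named list/vector of channel noise standard deviations
#'   (\code{ecg} in signal units, \code{z} in Ohm).
#' @param rr_jitter_sd fractional white jitter on RR intervals.
#' @param wave_noise_sd sd of the within-cycle waveform irregularity (flow
#'   noise, ~1 s correlation time), in units of the unit-depth waveform.
#' @param subject_id,group,sex metadata carried into the recording.
#' @param seed integer seed; the recording is deterministic given it.
#' @return list of class \code{subject_spec}.
#' @export
subject_spec <- function(posture = c("supine", "standing"),
                         mean_hr = NULL, resp_rate = NULL,
                         rsa_gain = NULL, phase_lead = 1.0,
                         duration = 300, fs = 250,
                         noise_sd = c(ecg = 0.01, z = 0.005),
                         rr_jitter_sd = 0.01,
                         wave_noise_sd = 0.03,
                         subject_id = "S000", group = "control",
                         sex = "M", seed = 1L) {
  posture <- match.arg(posture)
  preset <- if (posture == "supine") {
    list(mean_hr = 60, resp_rate = 0.23, rsa_gain = 0.25)
  } else {
    list(mean_hr = 75, resp_rate = 0.19, rsa_gain = 0.15)
  }
  spec <- list(
    posture = posture,
    mean_hr = mean_hr %||% preset$mean_hr,
    resp_rate = resp_rate %||% preset$resp_rate,
    rsa_gain = rsa_gain %||% preset$rsa_gain,
    phase_lead = phase_lead,
    duration = duration,
    fs = fs,
    noise_sd = noise_sd,
    rr_jitter_sd = rr_jitter_sd,
    wave_noise_sd = wave_noise_sd,
    subject_id = subject_id,
    group = group,
    sex = sex,
    seed = as.integer(seed)
  )
  validate_subject_spec(spec)
  structure(spec, class = "subject_spec")
}

validate_subject_spec <- function(spec) {
  if (spec$resp_rate <= 0.05 || spec$resp_rate >= 1) {
    stop("resp_rate must lie in (0.05, 1) Hz", call. = FALSE)
  }
  if (spec$mean_hr <= 30 || spec$mean_hr >= 220) {
    stop("mean_hr must lie in (30, 220) beats/min", call. = FALSE)
  }
  if (spec$duration < 60) stop("duration must be >= 60 s", call. = FALSE)
  if (spec$rsa_gain < 0) stop("rsa_gain must be >= 0", call. = FALSE)
  if (spec$fs <= 0) stop("fs must be positive", call. = FALSE)
  invisible(spec)
}

#' Simulate one raw two-channel recording
#'
#' Generates a 250 Hz single-lead-ECG-plus-impedance recording with known
#' ground truth. The impedance channel is a jittered breathing waveform
#' plus slow drift and noise; RR intervals are modulated by the breathing
#' waveform evaluated \code{phase_lead} seconds ahead (so heart-rate maxima
#' precede tidal-volume maxima when \code{phase_lead > 0}); the ECG places
#' a stylized raised-cosine QRS at each cumulative beat time over baseline
#' drift and noise.
#'
#' @param spec a \code{\link{subject_spec}}.
#' @return object of class \code{raw_recording}: list with
#'   \code{subject_id}, \code{posture}, \code{fs}, \code{ecg},
#'   \code{impedance}, \code{group}, \code{sex}, \code{duration} and a
#'   \code{truth} element (true R-peak times, inspiratory onsets,
#'   instantaneous heart rate on a 25 Hz grid, generating parameters).
#' @examples
#' rec <- simulate_subject(subject_spec(duration = 60, seed = 7))
#' rec
#' @export
simulate_subject <- function(spec) {
  if (!inherits(spec, "subject_spec")) spec <- do.call(subject_spec, spec)
  validate_subject_spec(spec)
  old_seed <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)

  fs <- spec$fs
  dur <- spec$duration
  n <- as.integer(round(dur * fs))
  t <- (seq_len(n) - 1L) / fs

  # --- respiration: phase oscillator with jittered cycle lengths ---------
  mean_T <- 1 / spec$resp_rate
  n_cyc <- ceiling((dur + 30) / mean_T) + 2L
  cyc <- rnorm(n_cyc, mean_T, 0.10 * mean_T)
  cyc <- pmax(pmin(cyc, 1.35 * mean_T), pmax(0.65 * mean_T, 1.0))
  onsets <- cumsum(c(0, cyc))
  # per-breath depth varies (~20% CV), as real tidal volumes do
  depth <- exp(rnorm(n_cyc, 0, 0.20))
  phase_at <- function(tt) {
    i <- findInterval(tt, onsets)
    i <- pmax(1L, pmin(i, n_cyc))
    2 * pi * (tt - onsets[i]) / cyc[i]
  }
  # within-cycle waveform irregularity (flow noise, ~1 s correlation time):
  # real volume curves are not smoothly extrapolatable inside a breath;
  # this enters the impedance channel only -- the vagal gate below couples
  # to the oscillatory waveform, not to measurement-level flow noise
  wn_fs <- 25
  wn_n <- as.integer((dur + 60) * wn_fs)
  wn_a <- exp(-1 / (wn_fs * 1.0))
  wnoise <- as.numeric(stats::filter(rnorm(wn_n, 0, spec$wave_noise_sd * sqrt(1 - wn_a^2)),
                                     wn_a, method = "recursive"))
  wn_t <- (seq_len(wn_n) - 1L) / wn_fs
  breath_at <- function(tt) {            # depth-scaled waveform, max mid-cycle
    i <- pmax(1L, pmin(findInterval(tt, onsets), n_cyc))
    irr_b <- approx(wn_t, wnoise, xout = pmin(pmax(tt, 0), max(wn_t)), rule = 2)$y
    depth[i] * 0.5 * (1 - cos(2 * pi * (tt - onsets[i]) / cyc[i])) + irr_b
  }
  # zero-mean depth-modulated carrier: what phasic vagal gating transfers
  # (slow depth/baseline shifts do not pass through the RSA pathway)
  osc_at <- function(tt) {
    i <- pmax(1L, pmin(findInterval(tt, onsets), n_cyc))
    depth[i] * 0.5 * (-cos(2 * pi * (tt - onsets[i]) / cyc[i]))
  }

  b <- breath_at(t)
  # slow stochastic baseline (vasomotion/posture sway): AR(1) with ~0.2 Hz
  # corner, sd ~0.03 Ohm -- gives the in-band broadband floor real
  # impedance recordings carry
  zar_sd <- 0.03
  ar_slow <- as.numeric(stats::filter(rnorm(n, 0, zar_sd * sqrt(1 - 0.995^2)),
                                      0.995, method = "recursive"))
  z <- 10 + 0.5 * b + ar_slow +
    0.05 * sin(2 * pi * 0.01 * t + runif(1, 0, 2 * pi)) +
    rnorm(n, 0, spec$noise_sd[["z"]])

  # --- RR intervals locked to respiration with phase lead ----------------
  # The heart-rate drive follows the zero-mean depth-modulated respiratory
  # oscillation (RSA amplitude scales with tidal volume), evaluated
  # phase_lead seconds ahead -- so the tachogram reflects both the timing
  # and the depth of a breath before the volume curve does.
  # Non-respiratory low-frequency variability is a stochastic
  # Ornstein-Uhlenbeck component (correlation time ~10 s, stationary sd
  # 2.5% of mean rate), the baro/thermoregulatory band real tachograms
  # carry.
  ou_fs <- 10
  ou_n <- as.integer((dur + 60) * ou_fs)
  ou_a <- exp(-1 / (ou_fs * 10))
  ou <- as.numeric(stats::filter(rnorm(ou_n, 0, 0.025 * sqrt(1 - ou_a^2)),
                                 ou_a, method = "recursive"))
  ou_t <- (seq_len(ou_n) - 1L) / ou_fs
  # the vagal gain itself wanders (autonomic state fluctuation, ~15 s
  # correlation time, 30% CV): the volume-to-tachogram mapping is not
  # time-invariant in real subjects
  vg_a <- exp(-1 / (ou_fs * 15))
  vgain <- 1 + as.numeric(stats::filter(rnorm(ou_n, 0, 0.30 * sqrt(1 - vg_a^2)),
                                        vg_a, method = "recursive"))
  hr_at <- function(tt) {
    tc <- pmin(pmax(tt, 0), max(ou_t))
    lf <- approx(ou_t, ou, xout = tc, rule = 2)$y
    g <- pmax(0.2, approx(ou_t, vgain, xout = tc, rule = 2)$y)
    spec$mean_hr * (1 + spec$rsa_gain * g * osc_at(tt + spec$phase_lead) + lf)
  }
  r_times <- numeric(0)
  tt <- runif(1, 0.2, 0.8)
  while (tt < dur - 0.2) {
    r_times <- c(r_times, tt)
    rr <- 60 / hr_at(tt)
    rr <- 60 / hr_at(tt + rr / 2)          # rate referenced to interval midpoint
    rr <- rr * (1 + rnorm(1, 0, spec$rr_jitter_sd))
    tt <- tt + max(0.25, rr)
  }

  # --- ECG: stylized QRS template at beat times --------------------------
  ecg <- 0.05 * sin(2 * pi * 0.1 * t + runif(1, 0, 2 * pi)) +
    rnorm(n, 0, spec$noise_sd[["ecg"]])
  half_w <- as.integer(round(0.012 * fs))          # QRS half-width ~12 ms
  tpl <- 0.5 * (1 + cos(seq(-pi, pi, length.out = 2L * half_w + 1L)))
  for (rt in r_times) {
    c0 <- as.integer(round(rt * fs)) + 1L
    lo <- max(1L, c0 - half_w)
    hi <- min(n, c0 + half_w)
    ecg[lo:hi] <- ecg[lo:hi] + tpl[(lo - c0 + half_w + 1L):(hi - c0 + half_w + 1L)]
  }

  t25 <- seq(0, dur - 1 / 25, by = 1 / 25)
  truth <- list(
    r_times = r_times,
    insp_onsets = onsets[onsets < dur],
    cycle_lengths = cyc,
    ihr25 = hr_at(t25),
    t25 = t25,
    spec = spec
  )
  structure(list(
    subject_id = spec$subject_id,
    posture = spec$posture,
    fs = fs,
    ecg = ecg,
    impedance = z,
    group = spec$group,
    sex = spec$sex,
    duration = dur,
    truth = truth
  ), class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("raw recording %s [%s, %s, %s]: %.0f s at %g Hz (%d samples/channel)\n",
              x$subject_id, x$posture, x$group, x$sex, x$duration, x$fs,
              length(x$ecg)))
  invisible(x)
}

#' Specification of a synthetic study cohort
#'
#' Group sizes default to the study composition (20 controls and 100
#' athletes split over Mitchell static/dynamic classes: IIIA 5, IB 24,
#' IIB 9, IIIB 12, IC 5, IIC 33, IIIC 12). Each subject receives two
#' posture sessions (supine, standing) with subject-level parameter draws;
#' the respiratory-sinus-arrhythmia gain increases with the Mitchell static
#' component for athletes, a synthetic convention that makes group labels
#' recoverable by downstream classification.
#'
#' @param group_sizes named integer vector of subjects per group.
#' @param duration per-session duration in seconds.
#' @param phase_lead heart-rate-leads-tidal-volume lead in seconds.
#' @param seed master seed; every subject seed derives from it.
#' @return list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(group_sizes = c(control = 20L, IIIA = 5L, IB = 24L,
                                        IIB = 9L, IIIB = 12L, IC = 5L,
                                        IIC = 33L, IIIC = 12L),
                        duration = 300, phase_lead = 1.0, seed = 1L) {
  stopifnot(all(group_sizes >= 0), !is.null(names(group_sizes)))
  structure(list(group_sizes = group_sizes, duration = duration,
                 phase_lead = phase_lead, seed = as.integer(seed)),
            class = "cohort_spec")
}

mitchell_static <- function(group) {
  ifelse(group == "control", NA_integer_,
         match(substr(group, 1, nchar(group) - 1L), c("I", "II", "III")))
}

#' Simulate a cohort of two-posture recordings
#'
#' Draws per-subject physiology (heart rate, breathing rate, RSA gain) from
#' group-dependent distributions and builds a \code{\link{subject_spec}}
#' pair (supine, standing) per subject. Recordings themselves are realized
#' lazily with \code{\link{simulate_subject}} on each spec, keeping memory
#' bounded for large cohorts.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return list of class \code{cohort}: \code{subjects} (data frame of
#'   generating parameters, one row per subject-posture) and \code{specs}
#'   (list of \code{subject_spec}).
#' @examples
#' coh <- simulate_cohort(cohort_spec(group_sizes = c(control = 2, IIC = 3),
#'                                    duration = 60))
#' nrow(coh$subjects)  # 10 = 5 subjects x 2 postures
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)

  groups <- rep(names(spec$group_sizes), times = spec$group_sizes)
  n_sub <- length(groups)
  specs <- list()
  rows <- list()
  for (i in seq_len(n_sub)) {
    g <- groups[i]
    stat <- mitchell_static(g)
    # synthetic convention: athletes gain RSA depth with static component
    rsa_base <- if (g == "control") 0.20 else 0.20 + 0.02 * stat
    hr_off <- rnorm(1, 0, 4)
    rr_off <- rnorm(1, 0, 0.015)
    rsa_i <- max(0.05, rsa_base + rnorm(1, 0, 0.02))
    sex <- if (runif(1) < 0.3) "F" else "M"
    sid <- sprintf("S%03d", i)
    for (posture in c("supine", "standing")) {
      preset_hr <- if (posture == "supine") 60 else 75
      preset_rr <- if (posture == "supine") 0.23 else 0.19
      rsa_p <- if (posture == "supine") rsa_i else 0.75 * rsa_i
      sseed <- (spec$seed + 7919L * i + ifelse(posture == "supine", 0L, 1L)) %% 2147483647L
      sp <- subject_spec(posture = posture,
                         mean_hr = preset_hr + hr_off,
                         resp_rate = min(0.95, max(0.06, preset_rr + rr_off)),
                         rsa_gain = rsa_p,
                         phase_lead = spec$phase_lead,
                         duration = spec$duration,
                         subject_id = sid, group = g, sex = sex,
                         seed = sseed)
      specs[[length(specs) + 1L]] <- sp
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sid, group = g, sex = sex, posture = posture,
        mean_hr = sp$mean_hr, resp_rate = sp$resp_rate,
        rsa_gain = sp$rsa_gain, phase_lead = sp$phase_lead,
        seed = sp$seed, stringsAsFactors = FALSE)
    }
  }
  structure(list(subjects = do.call(rbind, rows), specs = specs),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects x 2 postures (%d recordings)\n",
              nrow(x$subjects) / 2L, nrow(x$subjects)))
  print(table(x$subjects$group[x$subjects$posture == "supine"]))
  invisible(x)
}
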