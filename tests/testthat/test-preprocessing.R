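test_that("detrending removes offsets and sub-0.5 Hz wander but keeps QRS", {
  fs <- 250
  rec <- fixture_recording()
  clean <- rec$ecg
  t <- (seq_along(clean) - 1) / fs

  # constant offset: per-second window means near zero afterwards
  det <- detrend_ecg(clean + 2.0, fs)
  win_means <- tapply(det, (seq_along(det) - 1) %/% fs, mean)
  expect_lt(max(abs(win_means)), 0.05)

  # 0.3 Hz drift at R-wave amplitude: >= 20 dB power reduction at 0.3 Hz,
  # measured with an independent periodogram
  drift <- 1.0 * sin(2 * pi * 0.3 * t)
  det2 <- detrend_ecg(clean + drift, fs)
  band_power <- function(x, f0, half = 0.05) {
    sp <- Mod(fft(x))^2
    fr <- (seq_along(x) - 1) * fs / length(x)
    sum(sp[abs(fr - f0) < half])
  }
  red_db <- 10 * log10(band_power(clean + drift, 0.3) / band_power(det2, 0.3))
  expect_gt(red_db, 20)

  # near-idempotence on already-detrended input
  det3 <- detrend_ecg(det2, fs)
  expect_lt(sqrt(mean((det3 - det2)^2)) / sd(det2), 0.05)

  expect_error(detrend_ecg(rnorm(100), fs), "1 s")
})

test_that("Pan-Tompkins finds simulated R peaks to within 20 ms, noise-robustly", {
  fs <- 250
  rec <- fixture_recording()
  truth <- rec$truth$r_times
  det <- detrend_ecg(rec$ecg, fs)
  peaks <- detect_r_peaks(det, fs)

  expect_s3_class(peaks, "rpeak_series")
  expect_equal(length(peaks), length(truth))
  err <- vapply(truth, function(x) min(abs(as.numeric(peaks) - x)), numeric(1))
  expect_gte(mean(err <= 0.020), 0.99)
  # refractory guard
  expect_gt(min(diff(as.numeric(peaks))), 0.2)

  # white noise at SNR 10 dB: same peak count as clean
  set.seed(7)
  noisy <- rec$ecg + rnorm(length(rec$ecg), 0, sqrt(mean(rec$ecg^2) / 10))
  peaks_n <- detect_r_peaks(detrend_ecg(noisy, fs), fs)
  expect_equal(length(peaks_n), length(peaks))

  # degenerate input: empty series, not an error
  expect_length(detect_r_peaks(rep(0, 10 * fs), fs), 0)
})

test_that("impedance smoothing is a linear unit-gain averager", {
  fs <- 100
  # constant in, constant out
  expect_equal(smooth_impedance(rep(3.5, 1000), fs), rep(3.5, 1000))

  # white-noise variance shrinks by about the window length
  set.seed(11)
  x <- rnorm(10000)
  sm <- smooth_impedance(x, fs)
  expect_equal(var(sm) * fs, var(x), tolerance = 0.2)

  # analytic moving-average gain at 0.25 Hz (sinc factor)
  t <- (0:9999) / fs
  s <- sin(2 * pi * 0.25 * t)
  sm_s <- smooth_impedance(s, fs)
  gain_obs <- sd(sm_s[1000:9000]) / sd(s[1000:9000])
  gain_theory <- abs(sin(pi * 0.25 * 1) / (pi * 0.25 * 1))
  expect_equal(gain_obs, gain_theory, tolerance = 0.02)

  # linearity
  set.seed(12)
  a <- rnorm(500)
  b <- rnorm(500)
  expect_equal(smooth_impedance(2 * a + 3 * b, fs),
               2 * smooth_impedance(a, fs) + 3 * smooth_impedance(b, fs),
               tolerance = 1e-12)
})

test_that("breath-phase coding follows the signed derivative with a dead band", {
  fs <- 25
  t <- (0:(fs * 60 - 1)) / fs
  s <- sin(2 * pi * 0.25 * t)

  ph <- detect_breath_phases(s, fs, tau = 1e-9)
  expect_true(all(as.integer(ph) %in% c(-1L, 0L, 1L)))
  # rising half-cycles are +1, falling are -1; check away from extrema
  rising <- cos(2 * pi * 0.25 * t) > 0.2
  falling <- cos(2 * pi * 0.25 * t) < -0.2
  expect_true(all(as.integer(ph)[rising] == 1L))
  expect_true(all(as.integer(ph)[falling] == -1L))

  # antisymmetry under sign inversion
  ph_neg <- detect_breath_phases(-s, fs, tau = 1e-9)
  expect_equal(as.integer(ph_neg), -as.integer(ph))

  # inserted plateau is coded 0 under the robust dead band
  s2 <- c(s[1:200], rep(s[200], fs * 2), s[201:length(s)])
  ph2 <- detect_breath_phases(s2, fs)
  plateau <- 210:(200 + fs * 2 - 10)
  expect_true(all(as.integer(ph2)[plateau] == 0L))

  # constant input: all-zero phases
  expect_true(all(as.integer(detect_breath_phases(rep(1, 100), fs)) == 0L))
})

test_that("inspiratory onsets start each maximal inspiration run", {
  fs <- 10
  ph <- c(rep(0, 5), rep(1, 10), rep(-1, 10), rep(1, 12), rep(0, 3))
  on <- inspiratory_onsets(ph, fs, min_sep = 0)
  expect_equal(on, c(5, 25) / fs)
  # chatter within min_sep collapses to the first onset
  ph2 <- c(rep(1, 3), rep(0, 2), rep(1, 3), rep(-1, 10))
  expect_equal(inspiratory_onsets(ph2, fs, min_sep = 1), 0)
})
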