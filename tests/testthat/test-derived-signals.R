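test_that("instantaneous rates are interval-bounded interpolants", {
  grid <- seq(0, 20, by = 0.04)

  # constant RR of 1 s -> 60 beats/min everywhere
  expect_equal(compute_ihr(seq(0.5, 19.5, by = 1), grid),
               rep(60, length(grid)))

  # alternating 0.8/1.0 s intervals stay inside [60, 75]
  rr <- rep(c(0.8, 1.0), 12)
  peaks <- cumsum(c(0.3, rr))
  ihr <- compute_ihr(peaks, grid)
  expect_true(all(ihr >= 60 - 1e-9 & ihr <= 75 + 1e-9))

  # onsets every 4 s -> constant 15 breaths/min; 3/5 s alternation bounded
  expect_equal(compute_irr(seq(0, 60, by = 4), grid), rep(15, length(grid)))
  on2 <- cumsum(c(0, rep(c(3, 5), 8)))
  irr <- compute_irr(on2, grid)
  expect_true(all(irr >= 12 - 1e-9 & irr <= 20 + 1e-9))

  expect_error(compute_ihr(c(1, 2), grid), "3 R peaks")
})

test_that("rate recovery tracks the generator ground truth", {
  rec <- fixture_recording()
  ss <- fixture_signal_set()
  truth_ihr <- rec$truth$ihr25[seq_len(nrow(ss$series))]
  expect_gt(cor(ss$series[, "ihr"], truth_ihr), 0.9)

  # breathing-rate recovery against true cycle lengths
  true_on <- rec$truth$insp_onsets
  true_irr <- compute_irr(true_on, ss$t)
  expect_gt(cor(ss$series[, "irr"], true_irr), 0.9)
})

test_that("downsampling is anti-aliased with unit passband gain", {
  fs_in <- 25
  t <- (0:(fs_in * 400 - 1)) / fs_in
  # constant passes unchanged
  expect_equal(downsample(rep(2.5, 1000), 25, 2.5), rep(2.5, 100))

  # 0.2 Hz passband tone: amplitude preserved within 1%
  s <- sin(2 * pi * 0.2 * t)
  d <- downsample(s, 25, 2.5)
  expect_equal(max(abs(d[50:950])), 1, tolerance = 0.01)

  # 5 Hz tone (above the 1.25 Hz output Nyquist): residual < 1%
  s2 <- sin(2 * pi * 5 * t)
  d2 <- downsample(s2, 25, 2.5)
  expect_lt(max(abs(d2[50:950])), 0.01)

  # band-limited signal round-trips through spline interpolation within 2% RMS
  s3 <- sin(2 * pi * 0.2 * t) + 0.5 * cos(2 * pi * 0.35 * t)
  d3 <- downsample(s3, 25, 2.5)
  up <- spline(seq(0, by = 1 / 2.5, length.out = length(d3)), d3,
               xout = t)$y
  mid <- 500:(length(t) - 500)
  expect_lt(sqrt(mean((up[mid] - s3[mid])^2)) / sd(s3), 0.02)

  expect_error(downsample(rnorm(100), 25, 7), "integer factor")
})

test_that("beat sequences align RR intervals with per-peak covariates", {
  fs <- 250
  z <- rep(5, 4 * fs)
  ph <- rep(1L, 4 * fs)
  bs <- build_beat_sequence(c(1, 2, 3), z, ph, c(0.1, 1.4, 2.7), fs)
  expect_equal(bs$rr, c(1, 1))
  expect_equal(bs$amp, rep(5, 3))
  expect_equal(bs$phase_at_r, rep(1L, 3))
  expect_length(bs$irr_at_r, 3)

  # real pipeline: n peaks -> n-1 rr values, phases in the code set,
  # and a peak inside an inspiration run carries +1
  bs2 <- fixture_beat_sequence()
  expect_length(bs2$rr, length(bs2$t_rpeak) - 1L)
  expect_true(all(bs2$phase_at_r %in% c(-1L, 0L, 1L)))
  ss <- fixture_signal_set()
  idx <- round(bs2$t_rpeak * 250) + 1
  expect_equal(bs2$phase_at_r, as.integer(ss$phases)[idx])

  expect_error(build_beat_sequence(c(1, 2, 10), rep(1, 250), rep(0L, 250),
                                   c(0, 1, 2), 250),
               "outside")
})

test_that("identical recordings give bit-identical derived datasets", {
  r1 <- simulate_subject(subject_spec(duration = 70, seed = 55))
  r2 <- simulate_subject(subject_spec(duration = 70, seed = 55))
  expect_identical(r1$ecg, r2$ecg)
  s1 <- build_signal_set(r1)
  s2 <- build_signal_set(r2)
  expect_identical(s1$series, s2$series)
})

test_that("ADF screen separates white noise from random walks", {
  set.seed(21)
  white_ok <- mean(replicate(100, adf_stationarity(rnorm(1000))$stationary))
  expect_gte(white_ok, 0.95)

  set.seed(22)
  rw_flagged <- mean(replicate(100,
                               !adf_stationarity(cumsum(rnorm(1000)))$stationary))
  expect_gte(rw_flagged, 0.90)

  # trend-stationary series: non-stationary under the constant-only
  # regression, stationary once the trend term is included
  set.seed(23)
  x <- 0.01 * (1:800) + rnorm(800)
  expect_true(adf_stationarity(x, type = "trend")$stationary)

  expect_error(adf_stationarity(rep(1, 100)), "constant")
  expect_error(adf_stationarity(rnorm(20)), "short")
})
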