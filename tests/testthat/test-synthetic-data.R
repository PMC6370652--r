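test_that("subject simulation is seed-deterministic and honors its invariants", {
  s1 <- simulate_subject(subject_spec(duration = 60, seed = 5))
  s2 <- simulate_subject(subject_spec(duration = 60, seed = 5))
  expect_identical(s1$ecg, s2$ecg)
  expect_identical(s1$impedance, s2$impedance)

  rec <- fixture_recording()
  # generated RR mean within 2% of 60/mean_hr
  rr <- diff(rec$truth$r_times)
  expect_equal(mean(rr), 60 / rec$truth$spec$mean_hr, tolerance = 0.02)
  # breathing-cycle count within +/- 2 of resp_rate * duration
  n_cyc <- sum(rec$truth$insp_onsets < rec$duration)
  expect_lte(abs(n_cyc - rec$truth$spec$resp_rate * rec$duration), 2)

  expect_error(subject_spec(resp_rate = 1.5), "resp_rate")
  expect_error(subject_spec(mean_hr = 250), "mean_hr")
  expect_error(subject_spec(duration = 30), "duration")
  expect_error(subject_spec(rsa_gain = -1), "rsa_gain")
})

test_that("a positive phase lead puts the iHR maximum ahead of the TV maximum", {
  rec <- fixture_recording()
  ss <- build_signal_set(rec)
  tv <- scale(ss$series[, "tv"])[, 1]
  ihr <- scale(ss$series[, "ihr"])[, 1]
  cc <- ccf(ihr, tv, lag.max = 50, plot = FALSE)
  best_lag <- cc$lag[which.max(cc$acf)]
  # in ccf(x, y) a negative best lag means x leads y; the iHR curve should
  # lead TV by about the configured phase lead (1 s = 25 samples at 25 Hz)
  expect_lt(best_lag, 0)
  expect_lt(abs(-best_lag / 25 - rec$truth$spec$phase_lead), 0.6)
})

test_that("VAR simulation returns exact analytic causality for canonical systems", {
  sim0 <- simulate_var(array(0, c(2, 2, 1)), diag(2), 500, seed = 1)
  expect_true(all(sim0$analytic$gc == 0))

  sim1 <- simulate_var(var_coeffs_unidirectional(0.9), diag(2), 500, seed = 1)
  expect_equal(subset(sim1$analytic, from == "x" & to == "y")$gc, log(1.81),
               tolerance = 1e-6)
  expect_equal(subset(sim1$analytic, from == "y" & to == "x")$gc, 0,
               tolerance = 1e-6)

  # estimator agrees with the oracle on every bank model at large n
  for (m in var_bank()) {
    sim <- simulate_var(m$coeffs, m$noise, 10000, seed = 3)
    for (i in seq_len(nrow(sim$analytic))) {
      est <- gc_pairwise_conditional(sim$series, sim$analytic$from[i],
                                     sim$analytic$to[i],
                                     order = dim(m$coeffs)[3])
      expect_lt(abs(est$gc - sim$analytic$gc[i]), 0.05)
    }
  }

  unstable <- array(1.2, c(1, 1, 1))
  expect_error(simulate_var(unstable, diag(1), 100, seed = 1), "unstable")
})

test_that("cohort simulation mirrors the study composition reproducibly", {
  coh <- simulate_cohort(cohort_spec())
  expect_equal(nrow(coh$subjects), 240)  # 120 subjects x 2 postures
  sup <- coh$subjects[coh$subjects$posture == "supine", ]
  expect_equal(sum(sup$group == "control"), 20)
  expect_equal(sum(sup$group != "control"), 100)
  expect_equal(as.vector(table(sup$group)[c("IIIA", "IB", "IIB", "IIIB",
                                            "IC", "IIC", "IIIC")]),
               c(5, 24, 9, 12, 5, 33, 12))

  coh2 <- simulate_cohort(cohort_spec())
  expect_identical(coh$subjects, coh2$subjects)
  r1 <- simulate_subject(coh$specs[[1]])
  r2 <- simulate_subject(coh2$specs[[1]])
  expect_identical(r1$ecg, r2$ecg)

  # rsa separation by group built into the truth table
  expect_gt(median(sup$rsa_gain[sup$group != "control"]),
            median(sup$rsa_gain[sup$group == "control"]) - 0.02)
})

test_that("rsa_gain = 0 removes the heart-to-breathing coupling", {
  r <- vapply(1:15, function(s) {
    rec0 <- simulate_subject(subject_spec(duration = 120, seed = 200 + s,
                                          rsa_gain = 0))
    ss0 <- build_signal_set(rec0)
    s20 <- downsample_signal_set(ss0)
    rec1 <- simulate_subject(subject_spec(duration = 120, seed = 200 + s))
    ss1 <- build_signal_set(rec1)
    c(gc0 = gc_pairwise_conditional(ss0$series, "ihr", "tv", max_order = 10)$gc,
      gc1 = gc_pairwise_conditional(ss1$series, "ihr", "tv", max_order = 10)$gc,
      sig2p5 = gc_pairwise_conditional(s20$series, "ihr", "tv",
                                       max_order = 10)$significant)
  }, numeric(3))
  # effect size collapses without the RSA pathway (the 25 Hz F test itself
  # is anti-conservative on interpolated oversampled series, so the
  # calibration check lives at the near-critically-sampled 2.5 Hz rate)
  expect_lt(median(r["gc0", ]), 0.25 * median(r["gc1", ]))
  expect_lte(mean(r["sig2p5", ]), 0.2)
})
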