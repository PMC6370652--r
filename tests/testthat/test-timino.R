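test_that("additive-noise discovery recovers lagged non-Gaussian directions", {
  res <- vapply(1:30, function(s) {
    d <- sim_anm_pair(500, s, "uniform")
    r <- timino_fit_pair(d$x, d$y, seed = s)
    nrow(r$edges) == 1 && r$edges$from == "x"
  }, logical(1))
  expect_gte(mean(res), 0.8)
})

test_that("failed or ambiguous independence yields 'unidentified', never an error", {
  # hidden nonlinear confounder: both orientations leave dependent residuals
  set.seed(81)
  w <- runif(400, -1, 1)
  x <- w + 0.1 * runif(400, -1, 1)
  y <- w^2 + 0.1 * runif(400, -1, 1)
  r <- timino_fit_pair(x, y, seed = 1)
  expect_s3_class(r, "timino_result")
  expect_equal(r$status, "unidentified")
  expect_equal(nrow(r$edges), 0)
  expect_length(r$independence_p, 2)

  # gaussian instantaneous pair (unidentifiable regime) is mostly
  # unidentified, far more than the uniform-noise analogue
  unid <- function(noise) {
    mean(vapply(1:25, function(s) {
      d <- sim_anm_pair(400, s, noise, lagged = FALSE)
      timino_fit_pair(d$x, d$y, seed = s)$status == "unidentified"
    }, logical(1)))
  }
  expect_gt(unid("gaussian"), unid("uniform") + 0.2)

  expect_error(timino_fit_pair(rep(1, 200), rnorm(200)), "constant")
})

test_that("stricter independence levels weakly increase the unidentified rate", {
  rate_at <- function(alpha) {
    mean(vapply(1:15, function(s) {
      d <- sim_anm_pair(300, s, "uniform")
      timino_fit_pair(d$x, d$y, alpha_ind = alpha, seed = s)$status ==
        "unidentified"
    }, logical(1)))
  }
  expect_lte(rate_at(0.05), rate_at(0.4))
})

test_that("a result never carries both orientations and the census applies the two-case rule", {
  for (s in 1:5) {
    d <- sim_anm_pair(300, s, "uniform")
    r <- timino_fit_pair(d$x, d$y, seed = s)
    expect_lte(nrow(r$edges), 1)
  }

  mk <- function(subject, present_fwd, status = "identified") {
    data.frame(subject = subject, posture = "supine", group = "athlete",
               from = c("phase_at_r", "rr"), to = c("rr", "phase_at_r"),
               present = c(present_fwd, FALSE), status = status,
               stringsAsFactors = FALSE)
  }
  res <- rbind(mk("S1", TRUE), mk("S2", TRUE), mk("S3", FALSE, "unidentified"))
  cen <- cohort_link_census(res)
  fwd <- cen$counts[cen$counts$from == "phase_at_r" & cen$counts$to == "rr", ]
  expect_equal(fwd$n_present, 2)
  expect_equal(unique(cen$counts$n_unidentified_pairs), 1)
  # single-case links are suppressed from the graph view, kept in counts
  res1 <- rbind(mk("S1", TRUE))
  cen1 <- cohort_link_census(res1)
  expect_equal(nrow(cen1$graph), 0)
  expect_equal(sum(cen1$counts$n_present), 1)

  # ten subjects with the same single edge -> count 10
  res10 <- do.call(rbind, lapply(sprintf("S%02d", 1:10), mk, present_fwd = TRUE))
  cen10 <- cohort_link_census(res10)
  fwd10 <- cen10$counts[cen10$counts$from == "phase_at_r", ]
  expect_equal(fwd10$n_present, 10)
})

test_that("on RSA-coupled beat sequences the breathing-phase-to-RR direction dominates", {
  r <- vapply(1:8, function(s) {
    rec <- simulate_subject(subject_spec(posture = "standing", duration = 300,
                                         seed = 300 + s))
    ss <- build_signal_set(rec)
    bs <- build_beat_sequence(ss$r_peaks, ss$z_smooth, ss$phases,
                              ss$insp_onsets, rec$fs)
    tm <- timino_fit_pair(as.numeric(bs$phase_at_r[-1]), bs$rr, seed = s,
                          names = c("phase_at_r", "rr"))
    c(fwd = nrow(tm$edges) == 1 && tm$edges$from == "phase_at_r",
      rev = nrow(tm$edges) == 1 && tm$edges$from == "rr")
  }, logical(2))
  expect_gt(sum(r["fwd", ]), sum(r["rev", ]))
})

test_that("the distance-correlation permutation test is calibrated and detects dependence", {
  set.seed(91)
  p_null <- vapply(1:40, function(i) {
    dcor_perm_test(rnorm(100), rnorm(100), n_perm = 99, seed = i)$p_value
  }, numeric(1))
  expect_lt(mean(p_null < 0.05), 0.15)

  x <- rnorm(150)
  dep <- dcor_perm_test(x, x^2 + 0.1 * rnorm(150), n_perm = 199, seed = 1)
  expect_lt(dep$p_value, 0.05)
})
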