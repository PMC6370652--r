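test_that("link summaries use significant values only and count the rest as NA", {
  res <- data.frame(
    subject = sprintf("S%d", 1:5), posture = "supine",
    from = "ihr", to = "tv",
    significant = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    pi = c(1, 2, 3, 99, 99), stringsAsFactors = FALSE)
  s <- summarize_links(res)
  expect_equal(s$median, 2)
  expect_equal(s$mean, 2)
  expect_equal(s$na_count, 2)
  expect_equal(s$n_subjects, 5)

  # all non-significant: NA cells, na_count = cohort size
  res$significant <- FALSE
  s2 <- summarize_links(res)
  expect_true(is.na(s2$median) && is.na(s2$mean))
  expect_equal(s2$na_count, 5)

  # hand-computed medians/IQRs on a fixture cohort (spreadsheet oracle)
  vals <- c(2.1, 3.7, 1.4, 5.0, 2.8, 4.4)
  res3 <- data.frame(subject = sprintf("S%d", 1:6), posture = "standing",
                     from = "rr", to = "amp", significant = TRUE,
                     pi = vals, stringsAsFactors = FALSE)
  s3 <- summarize_links(res3)
  expect_equal(s3$median, median(vals))
  expect_equal(s3$iqr, unname(quantile(vals, 0.75) - quantile(vals, 0.25)))
  expect_equal(s3$sd, sd(vals))
})

test_that("rank-based group tests match exact references", {
  # identical groups: p = 1
  t1 <- group_tests(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(t1$p_value, 1)

  # complete separation with n = 3, 3: exact two-sided p = 0.1
  t2 <- group_tests(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(t2$p_value, 0.1)
  expect_equal(t2$method, "wilcoxon")

  # three identical groups: Kruskal-Wallis statistic 0, p = 1
  t3 <- group_tests(rep(c(5, 6, 7), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(t3$method, "kruskal-wallis")
  expect_equal(unname(t3$statistic), 0)
  expect_equal(t3$p_value, 1)
  expect_true(!is.null(t3$posthoc))

  expect_error(group_tests(1:3, rep("a", 3)), "2 groups")
  expect_error(group_tests(c(1, 2, 3), c("a", "a", "b")), ">= 2 values")
})

test_that("Cohen's kappa hits its closed-form anchors", {
  y <- factor(rep(c("a", "b"), each = 10))
  expect_equal(cohen_kappa(y, y), 1)
  expect_equal(cohen_kappa(factor(rep("a", 20), levels = c("a", "b")), y), 0)
  y4 <- factor(c("a", "a", "b", "b"))
  p4 <- factor(c("a", "b", "a", "b"))
  expect_equal(cohen_kappa(p4, y4), 0)
})

test_that("feature matrices key columns by method/link/posture and impute NA as 0 + indicator", {
  res <- data.frame(
    subject = rep(c("S1", "S2"), each = 2),
    posture = "supine", method = "time",
    from = "ihr", to = c("tv", "irr", "tv", "irr"),
    significant = c(TRUE, FALSE, TRUE, TRUE),
    pi = c(2.5, 0.4, 3.0, 0.6), stringsAsFactors = FALSE)
  labels <- data.frame(subject = c("S1", "S2"), label = c("athlete", "control"),
                       stringsAsFactors = FALSE)
  fm <- build_feature_matrix(res, labels)
  expect_equal(nrow(fm$x), 2)
  expect_true("time.ihr.tv.supine.pi" %in% names(fm$x))
  # S1's non-significant irr link imputed to 0 with indicator
  col <- fm$x[["time.ihr.irr.supine.pi"]]
  expect_equal(col, c(0, 0.6))
  expect_equal(fm$x[["time.ihr.irr.supine.pi.na"]], c(1, 0))

  # dependent beat-domain pair excluded
  res_dep <- data.frame(subject = "S1", posture = "supine", method = "extended",
                        from = "phase_at_r", to = "amp", significant = TRUE,
                        pi = 5, stringsAsFactors = FALSE)
  fm2 <- build_feature_matrix(rbind(res, res_dep), labels)
  expect_false(any(grepl("phase_at_r.amp", names(fm2$x), fixed = TRUE)))
})

test_that("RFE ranks a perfectly separating feature first and is seed-deterministic", {
  set.seed(100)
  n <- 40
  y <- factor(rep(c("athlete", "control"), each = n / 2))
  x <- data.frame(sep = ifelse(y == "athlete", 1, 0) + rnorm(n, 0, 0.05),
                  junk1 = rnorm(n), junk2 = rnorm(n), junk3 = rnorm(n),
                  junk4 = rnorm(n), junk5 = rnorm(n))
  fit <- rfe_classify(list(x = x, y = y), sizes = c(1, 2, 4), seed = 9)
  expect_true("sep" %in% fit$selected)
  expect_gte(fit$accuracy_mean, 95)
  expect_gte(fit$exploratory_accuracy, 95)
  expect_gte(fit$kappa, 0.9)

  fit2 <- rfe_classify(list(x = x, y = y), sizes = c(1, 2, 4), seed = 9)
  expect_identical(fit$selected, fit2$selected)
  expect_identical(fit$accuracy_mean, fit2$accuracy_mean)

  # label permutation: accuracy near the majority-class rate
  set.seed(101)
  yp <- sample(y)
  xp <- x[, paste0("junk", 1:5)]
  fitp <- rfe_classify(list(x = xp, y = yp), sizes = c(2, 4), seed = 10)
  # noise features on permuted labels: no skill above the 50% base rate
  # (small-sample CV commonly lands below chance here, never above)
  expect_lt(fitp$accuracy_mean, 65)

  expect_error(rfe_classify(list(x = x, y = factor(rep("a", n)))), "single class")
})
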