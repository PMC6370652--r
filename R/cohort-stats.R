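#' Per-link cohort summary of causal-link parameters
#'
#' Summarizes a per-subject results table into the per-(posture, link)
#' layout used for reporting: mean, SD, median and IQR over the subjects
#' whose link was statistically significant, plus the count of
#' non-significant (NA) results. Non-significant values contribute only to
#' the NA count; an all-non-significant link keeps NA summary cells.
#'
#' @param results data frame with columns \code{subject}, \code{posture},
#'   \code{from}, \code{to}, \code{significant} and the summarized value
#'   column.
#' @param value name of the value column (e.g. \code{"pi"},
#'   \code{"peak_g"}).
#' @return data frame keyed by (posture, link) with columns \code{posture},
#'   \code{from}, \code{to}, \code{mean}, \code{sd}, \code{median},
#'   \code{iqr}, \code{na_count}, \code{n_subjects}.
#' @export
summarize_links <- function(results, value = "pi") {
  need <- c("subject", "posture", "from", "to", "significant", value)
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  key <- unique(results[, c("posture", "from", "to")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sel <- results$posture == key$posture[i] &
      results$from == key$from[i] & results$to == key$to[i]
    v <- results[[value]][sel]
    sig <- results$significant[sel] & !is.na(v)
    vs <- v[sig]
    data.frame(posture = key$posture[i], from = key$from[i], to = key$to[i],
               mean = if (length(vs)) mean(vs) else NA_real_,
               sd = if (length(vs) > 1L) sd(vs) else NA_real_,
               median = if (length(vs)) median(vs) else NA_real_,
               iqr = if (length(vs)) unname(quantile(vs, 0.75) - quantile(vs, 0.25)) else NA_real_,
               na_count = sum(!sig),
               n_subjects = sum(sel),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$posture, out$from, out$to), , drop = FALSE]
}

#' Rank-based group comparisons of a causal parameter
#'
#' Two groups: Wilcoxon rank-sum test (exact where sample sizes permit and
#' no ties). More than two: Kruskal-Wallis, followed by pairwise post-hoc
#' Wilcoxon tests, reported unadjusted by default (a Holm-adjusted copy is
#' always included).
#'
#' @param values numeric vector (NAs dropped with their labels).
#' @param groups factor/character vector of group labels.
#' @return list with \code{method}, \code{p_value}, \code{statistic},
#'   \code{group_medians} and, for > 2 groups, \code{posthoc} (unadjusted
#'   pairwise p matrix) and \code{posthoc_holm}.
#' @examples
#' group_tests(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))$p_value
#' @export
group_tests <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(as.character(groups[keep]))
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2L)) stop("every group needs >= 2 values", call. = FALSE)
  med <- tapply(values, groups, median)
  if (nlevels(groups) == 2L) {
    wt <- suppressWarnings(wilcox.test(values ~ groups))
    return(list(method = "wilcoxon", p_value = wt$p.value,
                statistic = unname(wt$statistic), group_medians = med))
  }
  kw <- kruskal.test(values, groups)
  ph <- suppressWarnings(pairwise.wilcox.test(values, groups,
                                              p.adjust.method = "none"))
  ph_holm <- suppressWarnings(pairwise.wilcox.test(values, groups,
                                                   p.adjust.method = "holm"))
  list(method = "kruskal-wallis", p_value = kw$p.value,
       statistic = unname(kw$statistic), group_medians = med,
       posthoc = ph$p.value, posthoc_holm = ph_holm$p.value)
}

#' Feature matrix of causal parameters for classification
#'
#' Reshapes stacked per-subject link results from the three Granger
#' methods into one row per subject, one column per
#' (method, link, posture, quantity). Non-significant entries arrive as NA
#' and are imputed as 0, with a companion 0/1 missingness-indicator column
#' per feature (zero-variance indicators are dropped). The dependent
#' (phase_at_r, amp) beat-sequence links are excluded.
#'
#' @param results data frame with \code{subject}, \code{posture},
#'   \code{method}, \code{from}, \code{to}, \code{significant} and value
#'   columns (\code{pi}, and \code{peak_g}/\code{peak_f} for the spectral
#'   method).
#' @param labels data frame with \code{subject} and \code{label} columns.
#' @return list with \code{x} (numeric feature data frame), \code{y}
#'   (factor labels) of class \code{feature_matrix}.
#' @export
build_feature_matrix <- function(results, labels) {
  stopifnot(all(c("subject", "label") %in% names(labels)))
  dep <- results$method %in% c("extended", "timino") &
    ((results$from == "phase_at_r" & results$to == "amp") |
       (results$from == "amp" & results$to == "phase_at_r"))
  results <- results[!dep, , drop = FALSE]

  quantities <- intersect(c("pi", "peak_g", "peak_f"), names(results))
  subjects <- unique(labels$subject)
  cols <- list()
  for (q in quantities) {
    sub <- results[!is.na(results[[q]]), , drop = FALSE]
    if (q %in% c("peak_g", "peak_f")) sub <- sub[sub$method == "spectral", , drop = FALSE]
    if (q == "pi") sub <- sub[sub$method %in% c("time", "extended"), , drop = FALSE]
    if (!nrow(sub)) next
    fkey <- paste(sub$method, sub$from, sub$to, sub$posture, q, sep = ".")
    val <- ifelse(sub$significant, sub[[q]], NA_real_)
    for (fk in unique(fkey)) {
      sel <- fkey == fk
      v <- setNames(val[sel], sub$subject[sel])[subjects]
      miss <- as.numeric(is.na(v))
      v[is.na(v)] <- 0
      cols[[fk]] <- v
      if (var(miss) > 0) cols[[paste0(fk, ".na")]] <- miss
    }
  }
  x <- as.data.frame(cols, optional = TRUE, row.names = subjects)
  y <- factor(labels$label[match(subjects, labels$subject)])
  structure(list(x = x, y = y), class = "feature_matrix")
}

#' Recursive feature elimination with a random-forest kernel
#'
#' Backward elimination ranked by random-forest variable importance with
#' stratified 10-fold cross-validated performance at each candidate subset
#' size (via \code{caret::rfe}). Reports the selected features, the
#' cross-validated accuracy (mean and across-fold SD) and Cohen's Kappa at
#' the best size, plus a clearly-labeled exploratory (resubstitution)
#' accuracy/Kappa of a random forest fit on all data.
#'
#' @param features \code{feature_matrix} (or list with \code{x}, \code{y}).
#' @param sizes candidate subset sizes; defaults to a coarse grid up to the
#'   number of features.
#' @param folds number of CV folds.
#' @param seed seed controlling fold assignment and forest growth; fixed
#'   seed gives identical output.
#' @return list with \code{selected}, \code{accuracy_mean},
#'   \code{accuracy_sd}, \code{kappa}, \code{exploratory_accuracy},
#'   \code{exploratory_kappa}, \code{n_subjects}, \code{profile} (per-size
#'   CV results).
#' @export
rfe_classify <- function(features, sizes = NULL, folds = 10L, seed = 1L) {
  x <- as.data.frame(features$x)
  y <- features$y
  if (nlevels(droplevels(factor(y))) < 2L) stop("labels contain a single class",
                                                call. = FALSE)
  if (nrow(x) < 20L) stop("need at least 20 subjects", call. = FALSE)
  if (is.null(sizes)) {
    sizes <- unique(pmin(ncol(x), c(2, 4, 8, 12, 16, 24, 32, 48, 64)))
  }
  old_seed <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  ctrl <- caret::rfeControl(functions = caret::rfFuncs, method = "cv",
                            number = folds, verbose = FALSE)
  fit <- caret::rfe(x = x, y = y, sizes = sizes, rfeControl = ctrl)
  best <- fit$results[fit$results$Variables == fit$bestSubset, , drop = FALSE]

  set.seed(as.integer(seed) + 1L)
  rf_all <- randomForest::randomForest(x = x, y = y)
  pred <- predict(rf_all, x)
  list(selected = caret::predictors(fit),
       accuracy_mean = 100 * best$Accuracy[1L],
       accuracy_sd = 100 * best$AccuracySD[1L],
       kappa = best$Kappa[1L],
       exploratory_accuracy = 100 * mean(pred == y),
       exploratory_kappa = cohen_kappa(pred, y),
       n_subjects = nrow(x),
       profile = fit$results)
}

#' Cohen's Kappa for two label vectors
#'
#' Chance-corrected agreement: (observed - expected) / (1 - expected),
#' with expected agreement from the marginal label frequencies. Returns 0
#' when expected agreement is 1 (e.g. both vectors constant).
#'
#' @param pred,obs factors/vectors of equal length.
#' @return Kappa in [-1, 1].
#' @export
cohen_kappa <- function(pred, obs) {
  lev <- union(levels(factor(pred)), levels(factor(obs)))
  pred <- factor(pred, levels = lev)
  obs <- factor(obs, levels = lev)
  tab <- table(pred, obs) / length(pred)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(0)
  (po - pe) / (1 - pe)
}
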