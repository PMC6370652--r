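#' Pairwise additive-noise causal discovery for time series
#'
#' TiMINo-style discovery for a variable pair: each orientation fits an
#' additive time-series model of the effect on lags 1..max_lag of itself
#' and lags 0..max_lag of the putative cause, then tests whether the fit's
#' residuals are independent of the cause block (distance-correlation
#' permutation test). An orientation is accepted only when exactly one of
#' the two passes the independence test; otherwise the case is returned as
#' "unidentified" -- never an error. Identifiability rests on the
#' restricted (additive-noise) model class: with non-Gaussian noise the
#' anticausal fit leaves residual dependence.
#'
#' @param x,y numeric sequences of equal length (>= 100).
#' @param max_lag maximum lag (default 4).
#' @param model "linear" additive model (default) or "spline", which adds
#'   quadratic and cubic terms of the cause lags -- a light nonlinearity
#'   suited to sequences of a few hundred beats, where flexible smoothers
#'   overfit.
#' @param alpha_ind independence-test level; residuals failing it reject
#'   the orientation.
#' @param n_perm permutations for the distance-correlation test.
#' @param seed seed for the permutation draw.
#' @param names variable names for the report.
#' @return object of class \code{timino_result}: list with
#'   \code{variables}, \code{edges} (data frame \code{from}, \code{to};
#'   empty when unidentified), \code{status}
#'   ("identified"/"unidentified"), \code{independence_p} (named vector,
#'   one entry per orientation), \code{max_lag}.
#' @examples
#' set.seed(1)
#' n <- 300
#' x <- as.numeric(arima.sim(list(ar = 0.5), n, innov = runif(n, -1, 1)))
#' y <- stats::filter(0.8 * x, 0.5, method = "recursive") +
#'   runif(n, -0.3, 0.3)
#' timino_fit_pair(x, as.numeric(y), seed = 1)
#' @export
timino_fit_pair <- function(x, y, max_lag = 4L, model = c("linear", "spline"),
                            alpha_ind = 0.05, n_perm = 200L, seed = 1L,
                            names = c("x", "y")) {
  model <- match.arg(model)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("sequences must have equal length", call. = FALSE)
  if (length(x) < 100L) stop("sequences too short (need >= 100)", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("constant input", call. = FALSE)

  p1 <- timino_orientation(x, y, max_lag, model, n_perm, seed)        # x -> y
  p2 <- timino_orientation(y, x, max_lag, model, n_perm, seed + 1L)   # y -> x
  pvals <- setNames(c(p1, p2), c(paste(names[1L], "->", names[2L]),
                                 paste(names[2L], "->", names[1L])))
  pass <- pvals >= alpha_ind
  if (sum(pass) == 1L) {
    dir <- which(pass)
    edge <- if (dir == 1L) data.frame(from = names[1L], to = names[2L],
                                      stringsAsFactors = FALSE)
            else data.frame(from = names[2L], to = names[1L],
                            stringsAsFactors = FALSE)
    status <- "identified"
  } else {
    edge <- data.frame(from = character(0), to = character(0),
                       stringsAsFactors = FALSE)
    status <- "unidentified"
  }
  structure(list(variables = names, edges = edge, status = status,
                 independence_p = pvals, max_lag = as.integer(max_lag)),
            class = "timino_result")
}

#' @export
print.timino_result <- function(x, ...) {
  if (x$status == "identified") {
    cat(sprintf("TiMINo: %s -> %s (independence p: %s)\n",
                x$edges$from, x$edges$to,
                paste(sprintf("%s %.3f", names(x$independence_p),
                              x$independence_p), collapse = "; ")))
  } else {
    cat(sprintf("TiMINo: unidentified (independence p: %s)\n",
                paste(sprintf("%s %.3f", names(x$independence_p),
                              x$independence_p), collapse = "; ")))
  }
  invisible(x)
}

# residual-independence p-value for the orientation cause -> effect: the
# fit residuals must be independent of the cause series as a whole, so the
# test block spans cause values from max_lag past to max_lag ahead --
# dependence of anticausal residuals on the cause's future is the signal
# that rejects the wrong orientation
timino_orientation <- function(cause, effect, max_lag, model, n_perm, seed) {
  p <- as.integer(max_lag)
  n <- length(cause)
  X2 <- cbind(effect, cause)
  colnames(X2) <- c("eff", "cau")
  base <- lag_design(X2, p, include_lag0_of = "cau")
  rows_y <- (p + 1L):n
  yv <- effect[rows_y]
  cause_reg <- base[, grepl("^cau\\.", colnames(base)), drop = FALSE]
  if (model == "spline") base <- cbind(base, cause_reg^2, cause_reg^3)
  X <- cbind(1, base)
  qrX <- qr(X)
  res <- qr.resid(qrX, yv)

  # align residual rows that have a full +/- max_lag cause window
  keep <- seq_len(n - 2L * p)                   # rows t = p+1 .. n-p
  shifts <- (-p):p                              # cause at t+p .. t-p
  block <- vapply(shifts, function(s) cause[rows_y[keep] + s], numeric(length(keep)))
  dcor_max_perm_test(res[keep], block, n_perm = n_perm, seed = seed)$p_value
}

# max-statistic permutation test: distance correlation of `a` against each
# column of `b` separately, maximum over columns as the test statistic
# (single-shift dependence is not diluted by the other shifts; the
# permutation null controls the family-wise error exactly). Rows are
# subsampled beyond `max_rows` to bound the O(n^2) distance matrices.
dcor_max_perm_test <- function(a, b, n_perm = 200L, seed = 1L,
                               max_rows = 350L) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b))
  old_seed <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  if (nrow(a) > max_rows) {
    rows <- sort(sample.int(nrow(a), max_rows))
    a <- a[rows, , drop = FALSE]
    b <- b[rows, , drop = FALSE]
  }
  n <- nrow(a)
  A <- dcenter(as.matrix(stats::dist(a)))
  Bs <- lapply(seq_len(ncol(b)), function(j) dcenter(as.matrix(stats::dist(b[, j]))))
  dvar_a <- mean(A * A)
  dvar_b <- vapply(Bs, function(B) mean(B * B), numeric(1))
  stat_of <- function(Am) {
    max(vapply(seq_along(Bs), function(j) {
      den <- dvar_a * dvar_b[j]
      if (den <= 0) 0 else sqrt(max(0, mean(Am * Bs[[j]])) / sqrt(den))
    }, numeric(1)))
  }
  obs <- stat_of(A)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample.int(n)
    if (stat_of(A[perm, perm]) >= obs) exceed <- exceed + 1L
  }
  list(dcor_max = obs, p_value = (exceed + 1L) / (n_perm + 1L))
}

#' Distance-correlation permutation test of independence
#'
#' Classic double-centered distance covariance between a vector (or
#' matrix) pair, with a permutation null obtained by permuting the rows of
#' the first argument. The p-value uses the add-one permutation
#' convention.
#'
#' @param a,b numeric vectors or matrices with matching row counts.
#' @param n_perm number of permutations.
#' @param seed permutation seed.
#' @return list with \code{dcor} and \code{p_value}.
#' @export
dcor_perm_test <- function(a, b, n_perm = 200L, seed = 1L) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b))
  n <- nrow(a)
  A <- dcenter(as.matrix(stats::dist(a)))
  B <- dcenter(as.matrix(stats::dist(b)))
  dcov2 <- mean(A * B)
  dvar_a <- mean(A * A)
  dvar_b <- mean(B * B)
  dcor_obs <- if (dvar_a * dvar_b <= 0) 0 else sqrt(max(0, dcov2) / sqrt(dvar_a * dvar_b))

  old_seed <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample.int(n)
    dcov2_p <- mean(A[perm, perm] * B)
    stat_p <- if (dvar_a * dvar_b <= 0) 0 else sqrt(max(0, dcov2_p) / sqrt(dvar_a * dvar_b))
    if (stat_p >= dcor_obs) exceed <- exceed + 1L
  }
  list(dcor = dcor_obs, p_value = (exceed + 1L) / (n_perm + 1L))
}

dcenter <- function(D) {
  rm <- rowMeans(D)
  gm <- mean(D)
  D - outer(rm, rm, "+") + gm
}

#' TiMINo over the non-dependent pairs of a beat sequence
#'
#' Runs \code{\link{timino_fit_pair}} on every unordered variable pair of
#' a beat-aligned matrix, excluding the deterministically dependent
#' (phase_at_r, amp) pair.
#'
#' @param seq \code{beat_sequence} or beat-aligned matrix.
#' @inheritParams timino_fit_pair
#' @return data frame with one row per orientation: \code{from},
#'   \code{to}, \code{present} (edge accepted), \code{independence_p},
#'   \code{status} of the pair.
#' @export
timino_all_pairs <- function(seq, max_lag = 4L, model = "linear",
                             alpha_ind = 0.05, n_perm = 200L, seed = 1L) {
  x <- if (inherits(seq, "beat_sequence")) beat_matrix(seq) else as_channel_matrix(seq)
  channels <- colnames(x)
  combs <- utils::combn(channels, 2L)
  rows <- list()
  for (j in seq_len(ncol(combs))) {
    v1 <- combs[1L, j]; v2 <- combs[2L, j]
    if (setequal(c(v1, v2), c("phase_at_r", "amp"))) next
    r <- timino_fit_pair(x[, v1], x[, v2], max_lag = max_lag, model = model,
                         alpha_ind = alpha_ind, n_perm = n_perm,
                         seed = seed + 13L * j, names = c(v1, v2))
    for (d in 1:2) {
      from <- if (d == 1L) v1 else v2
      to <- if (d == 1L) v2 else v1
      rows[[length(rows) + 1L]] <- data.frame(
        from = from, to = to, method = "timino",
        present = nrow(r$edges) == 1L && r$edges$from == from,
        independence_p = unname(r$independence_p[d]),
        status = r$status, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort census of TiMINo links
#'
#' Counts, per group/posture stratum, how often each directed link was
#' accepted and how often the pair was left unidentified. The graph view
#' keeps only links accepted in at least \code{min_cases} recordings
#' (default 2); raw counts always retain every link.
#'
#' @param results data frame of per-recording \code{\link{timino_all_pairs}}
#'   rows with added \code{subject}, \code{posture}, \code{group} columns.
#' @param by stratification columns present in \code{results}.
#' @param min_cases graph-view inclusion threshold.
#' @return list with \code{counts} (per-stratum link counts with
#'   \code{n_present} and \code{n_unidentified}) and \code{graph} (the
#'   thresholded view).
#' @export
cohort_link_census <- function(results, by = c("group", "posture"),
                               min_cases = 2L) {
  stopifnot(nrow(results) >= 1L, all(c(by, "subject") %in% names(results)))
  key <- interaction(results[by], drop = TRUE, sep = "|")
  out <- list()
  for (lev in levels(key)) {
    sub <- results[key == lev, , drop = FALSE]
    links <- unique(sub[, c("from", "to")])
    cnt <- vapply(seq_len(nrow(links)), function(i) {
      sum(sub$present[sub$from == links$from[i] & sub$to == links$to[i]])
    }, integer(1))
    n_unid <- length(unique(paste(sub$subject, sub$from, sub$to)[sub$status == "unidentified"])) / 2L
    strat <- sub[1L, by, drop = FALSE]
    out[[lev]] <- cbind(strat, links, n_present = cnt,
                        n_unidentified_pairs = round(n_unid),
                        row.names = NULL)
  }
  counts <- do.call(rbind, out)
  rownames(counts) <- NULL
  graph <- counts[counts$n_present >= min_cases, , drop = FALSE]
  rownames(graph) <- NULL
  list(counts = counts, graph = graph)
}
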