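#' Extended (zero-lag) Granger causality on beat-by-beat sequences
#'
#' Granger framework for beat-indexed variables that also counts
#' instantaneous (within-beat) transfer: the restricted model regresses the
#' effect on lags 1..max_lag of itself and of the conditioning variables;
#' the full model adds lags 0..max_lag of the cause. The zero-lag term
#' captures effects occurring inside the same cardiac cycle, which a
#' classic lagged-only model cannot see. The F test counts the
#' \code{max_lag + 1} added regressors.
#'
#' @param seq a \code{\link{build_beat_sequence}} result, or a numeric
#'   matrix of beat-aligned variables.
#' @param from,to variable names among the matrix columns (for a
#'   \code{beat_sequence}: \code{rr}, \code{amp}, \code{irr_at_r},
#'   \code{phase_at_r}).
#' @param max_lag maximum beat lag (default 4, roughly half to one
#'   respiratory cycle).
#' @param conditional include lags of the remaining variables in both
#'   models.
#' @param instantaneous include the zero-lag cause term (the extension);
#'   \code{FALSE} gives the classic lagged-only variant.
#' @param alpha significance level.
#' @return one-row data frame of class \code{gc_result} with
#'   \code{method = "extended"} (or \code{"beat_classic"}), an
#'   \code{instantaneous} flag, \code{gc}, \code{p_value},
#'   \code{significant} and \code{pi}.
#' @export
extended_gc <- function(seq, from, to, max_lag = 4L, conditional = TRUE,
                        instantaneous = TRUE, alpha = 0.05) {
  x <- if (inherits(seq, "beat_sequence")) beat_matrix(seq) else as_channel_matrix(seq)
  channels <- colnames(x)
  from <- resolve_channel(from, channels)
  to <- resolve_channel(to, channels)
  if (from == to) stop("'from' and 'to' must differ", call. = FALSE)
  const <- channels[apply(x, 2, sd) == 0]
  if (length(const)) {
    stop(sprintf("constant variable '%s'; causality undefined", const[1L]),
         call. = FALSE)
  }
  p <- as.integer(max_lag)
  if (nrow(x) < 20L * p) stop("sequence too short for the requested max lag",
                              call. = FALSE)

  cond <- if (conditional) setdiff(channels, c(from, to)) else character(0)
  keep <- c(to, cond)
  base <- lag_design(x[, c(keep, from), drop = FALSE], p)
  rows_y <- (p + 1L):nrow(x)
  y <- x[rows_y, to]
  n <- length(y)

  base_cols <- colnames(base)
  restr_cols <- base_cols[!grepl(paste0("^", from, "\\.l"), base_cols)]
  full_cols <- base_cols
  X_r <- cbind(const = 1, base[, restr_cols, drop = FALSE])
  X_f <- cbind(const = 1, base[, full_cols, drop = FALSE])
  if (instantaneous) X_f <- cbind(X_f, lag0 = x[rows_y, from])

  rss_r <- ols_rss(X_r, y)
  rss_f <- ols_rss(X_f, y)
  df_num <- ncol(X_f) - ncol(X_r)
  df_den <- n - ncol(X_f)
  pval <- gc_ftest(rss_r, rss_f, df_num, df_den)
  gc <- max(0, log(rss_r / rss_f))
  new_gc_result(from, to, order_used = p, gc = gc, p_value = pval,
                alpha = alpha, n_obs = n,
                method = if (instantaneous) "extended" else "beat_classic",
                extra = data.frame(instantaneous = instantaneous))
}

#' Extended GC over all ordered variable pairs of a beat sequence
#'
#' @inheritParams extended_gc
#' @param exclude_dependent drop the (phase_at_r, amp) pairs, which are
#'   deterministically dependent through the breathing waveform, from the
#'   output (they remain computable individually).
#' @return data frame of \code{gc_result} rows.
#' @export
extended_all_links <- function(seq, max_lag = 4L, alpha = 0.05,
                               exclude_dependent = FALSE) {
  x <- if (inherits(seq, "beat_sequence")) beat_matrix(seq) else as_channel_matrix(seq)
  channels <- colnames(x)
  pairs <- expand.grid(from = channels, to = channels,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  if (exclude_dependent) {
    dep <- (pairs$from == "phase_at_r" & pairs$to == "amp") |
      (pairs$from == "amp" & pairs$to == "phase_at_r")
    pairs <- pairs[!dep, ]
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    extended_gc(x, pairs$from[i], pairs$to[i], max_lag = max_lag,
                alpha = alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Matrix of instantaneous (zero-lag) effects
#'
#' For each ordered variable pair, tests the zero-lag cause coefficient in
#' the full extended model (t test). The diagonal is undefined and
#' reported as NA. The orientation of a zero-lag link follows the
#' regression direction and is not symmetrized; instantaneous coupling is
#' inherently direction-ambiguous and both cells of a pair may flag.
#'
#' @inheritParams extended_gc
#' @param alpha significance level for flagging.
#' @return list with \code{p_values} and logical \code{significant}
#'   matrices (rows = cause, columns = effect), both with NA diagonals.
#' @export
instantaneous_effect_matrix <- function(seq, max_lag = 4L, alpha = 0.05) {
  x <- if (inherits(seq, "beat_sequence")) beat_matrix(seq) else as_channel_matrix(seq)
  channels <- colnames(x)
  k <- length(channels)
  pmat <- matrix(NA_real_, k, k, dimnames = list(from = channels, to = channels))
  p <- as.integer(max_lag)
  rows_y <- (p + 1L):nrow(x)
  base <- lag_design(x, p)
  for (from in channels) {
    for (to in setdiff(channels, from)) {
      X <- cbind(const = 1, base, lag0 = x[rows_y, from])
      y <- x[rows_y, to]
      qrX <- qr(X)
      if (qrX$rank < ncol(X)) stop("rank-deficient design (constant variable?)",
                                   call. = FALSE)
      beta <- qr.coef(qrX, y)
      res <- qr.resid(qrX, y)
      df <- length(y) - ncol(X)
      s2 <- sum(res^2) / df
      cov_last <- chol2inv(qr.R(qrX))[ncol(X), ncol(X)]
      tstat <- beta[["lag0"]] / sqrt(s2 * cov_last)
      pmat[from, to] <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
    }
  }
  list(p_values = pmat, significant = pmat < alpha)
}
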