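#' Fit a vector autoregressive (VAR) model with BIC order selection
#'
#' Ordinary-least-squares VAR fit with an intercept. The model order is
#' chosen by minimizing the Bayesian Information Criterion over
#' \code{1:max_order}; all candidate orders are scored on the common
#' estimation sample implied by \code{max_order}, then the winning order is
#' refit on its own full sample.
#'
#' @param x numeric matrix or data frame, one column per channel.
#' @param max_order maximum candidate order (>= 1).
#' @param order optional fixed order; skips BIC selection when given.
#' @return an object of class \code{var_model}: list with elements
#'   \code{order}, \code{A} (k x k x p coefficient array, \code{A[i, j, l]}
#'   is the effect of channel j at lag l on channel i), \code{intercept},
#'   \code{resid_cov}, \code{n_obs}, \code{channels}, \code{stable}
#'   (spectral radius of the companion matrix < 1) and \code{bic}
#'   (per-order scores).
#' @examples
#' x <- simulate_var(var_coeffs_unidirectional(0.9), diag(2), n = 500, seed = 1)
#' fit_var(x$series, max_order = 6)
#' @export
fit_var <- function(x, max_order = 20L, order = NULL) {
  x <- as_channel_matrix(x)
  k <- ncol(x)
  n <- nrow(x)
  channels <- colnames(x)
  const_sd <- apply(x, 2, sd)
  if (any(const_sd == 0)) {
    stop(sprintf("channel '%s' is constant; VAR design is rank-deficient",
                 channels[which(const_sd == 0)[1L]]), call. = FALSE)
  }
  max_order <- as.integer(max_order)
  if (max_order < 1L) stop("max_order must be >= 1", call. = FALSE)
  if (n <= k * max_order + k + 1L) {
    stop("series too short for the requested maximum order", call. = FALSE)
  }

  bic <- NULL
  if (is.null(order)) {
    sc <- var_order_scan(x, max_order)
    bic <- sc$bic
    order <- which.min(bic)
  }
  order <- as.integer(order)

  fit <- var_ols(x, order)
  A <- array(0, dim = c(k, k, order),
             dimnames = list(channels, channels, NULL))
  # var_ols returns B as (1 + k*order) x k: intercept row then lag-major rows
  for (l in seq_len(order)) {
    rows <- 1L + (l - 1L) * k + seq_len(k)
    A[, , l] <- t(fit$B[rows, , drop = FALSE])
  }
  structure(list(
    order = order,
    A = A,
    intercept = fit$B[1L, ],
    resid_cov = fit$resid_cov,
    n_obs = fit$n_obs,
    channels = channels,
    stable = var_spectral_radius(A) < 1,
    bic = bic
  ), class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("VAR(%d) over %d channels (%s), %d observations\n",
              x$order, length(x$channels), paste(x$channels, collapse = ", "),
              x$n_obs))
  cat(sprintf("stable: %s; residual sds: %s\n", x$stable,
              paste(signif(sqrt(diag(x$resid_cov)), 3), collapse = ", ")))
  invisible(x)
}

# OLS fit at fixed order on the maximal sample; B is (1 + k*p) x k
var_ols <- function(x, p) {
  k <- ncol(x)
  X <- cbind(const = 1, lag_design(x, p))
  Y <- x[(p + 1L):nrow(x), , drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient VAR design", call. = FALSE)
  B <- qr.coef(qrX, Y)
  E <- Y - X %*% B
  n_obs <- nrow(Y)
  list(B = B, resid_cov = crossprod(E) / (n_obs - ncol(X)),
       rss = colSums(E^2), n_obs = n_obs)
}

# score all orders 1..max_order on the common sample via one Gram matrix
var_order_scan <- function(x, max_order) {
  k <- ncol(x)
  X <- cbind(const = 1, lag_design(x, max_order))
  Y <- x[(max_order + 1L):nrow(x), , drop = FALSE]
  n <- nrow(Y)
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  YtY <- crossprod(Y)
  bic <- numeric(max_order)
  for (p in seq_len(max_order)) {
    idx <- c(1L, 1L + seq_len(k * p))
    B <- solve(XtX[idx, idx, drop = FALSE], XtY[idx, , drop = FALSE])
    S <- (YtY - crossprod(XtY[idx, , drop = FALSE], B)) / n
    ld <- determinant(S, logarithm = TRUE)$modulus
    bic[p] <- as.numeric(ld) + log(n) * (p * k^2 + k) / n
  }
  list(bic = bic)
}

var_spectral_radius <- function(A) {
  k <- dim(A)[1L]
  p <- dim(A)[3L]
  comp <- matrix(0, k * p, k * p)
  for (l in seq_len(p)) comp[seq_len(k), (l - 1L) * k + seq_len(k)] <- A[, , l]
  if (p > 1L) comp[(k + 1L):(k * p), seq_len(k * (p - 1L))] <- diag(k * (p - 1L))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Pairwise-conditional time-domain Granger causality
#'
#' G-causality of channel \code{from} onto channel \code{to}, conditioned on
#' every remaining channel: the log ratio of the residual variance of the
#' restricted model (own lags + conditioning lags) to that of the full model
#' (adds the cause's lags). Order is chosen by BIC on the full system unless
#' fixed. Significance is an F test on the nested models at
#' \code{alpha = 0.05}; prediction improvement is
#' \code{100 * exp(gc) - 100} per cent.
#'
#' @param x numeric matrix/data frame of channels.
#' @param from,to channel names or indices (cause, effect).
#' @param max_order maximum VAR order for BIC selection.
#' @param order optional fixed order.
#' @param alpha significance level for the F test.
#' @return one-row data frame of class \code{gc_result}: \code{from},
#'   \code{to}, \code{order_used}, \code{gc}, \code{p_value},
#'   \code{significant}, \code{pi} (per cent), \code{n_obs},
#'   \code{method = "time"}. Negative finite-sample estimates are clipped to
#'   zero before the prediction improvement is formed.
#' @examples
#' sim <- simulate_var(var_coeffs_unidirectional(0.9), diag(2), 2000, seed = 2)
#' gc_pairwise_conditional(sim$series, from = "x", to = "y", max_order = 6)
#' @export
gc_pairwise_conditional <- function(x, from, to, max_order = 20L,
                                    order = NULL, alpha = 0.05) {
  x <- as_channel_matrix(x)
  channels <- colnames(x)
  from <- resolve_channel(from, channels)
  to <- resolve_channel(to, channels)
  if (from == to) stop("'from' and 'to' must differ", call. = FALSE)
  if (ncol(x) < 2L) stop("need at least two channels", call. = FALSE)

  if (is.null(order)) {
    sc <- var_order_scan(x, as.integer(max_order))
    order <- which.min(sc$bic)
  }
  p <- as.integer(order)
  k <- ncol(x)

  X <- cbind(const = 1, lag_design(x, p))
  y <- x[(p + 1L):nrow(x), to]
  n <- length(y)
  full_cols <- seq_len(ncol(X))
  drop_cols <- 1L + outer(match(from, channels), (seq_len(p) - 1L) * k, "+")
  restr_cols <- setdiff(full_cols, as.integer(drop_cols))

  rss_f <- ols_rss(X[, full_cols, drop = FALSE], y)
  rss_r <- ols_rss(X[, restr_cols, drop = FALSE], y)
  if (!is.finite(rss_f) || rss_f <= 0) stop("non-finite variance ratio", call. = FALSE)

  gc_raw <- log(rss_r / rss_f)
  df_num <- p
  df_den <- n - length(full_cols)
  pval <- gc_ftest(rss_r, rss_f, df_num, df_den)

  gc <- max(0, gc_raw)
  new_gc_result(from, to, order_used = p, gc = gc, p_value = pval,
                alpha = alpha, n_obs = n, method = "time")
}

ols_rss <- function(X, y) {
  fit <- qr(X)
  if (fit$rank < ncol(X)) stop("rank-deficient design in GC regression", call. = FALSE)
  sum(qr.resid(fit, y)^2)
}

gc_ftest <- function(rss_r, rss_f, df_num, df_den) {
  if (df_num <= 0 || df_den <= 0) stop("non-positive degrees of freedom", call. = FALSE)
  f <- ((rss_r - rss_f) / df_num) / (rss_f / df_den)
  pf(max(0, f), df_num, df_den, lower.tail = FALSE)
}

new_gc_result <- function(from, to, order_used, gc, p_value, alpha, n_obs,
                          method, extra = NULL) {
  out <- data.frame(from = from, to = to, method = method,
                    order_used = order_used, gc = gc, p_value = p_value,
                    significant = p_value < alpha,
                    pi = prediction_improvement(gc), n_obs = n_obs,
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  class(out) <- c("gc_result", class(out))
  out
}

#' F-test p-value for a G-causality estimate
#'
#' Converts a G-causality value (log residual-variance ratio of nested
#' models) back to the restricted/full residual-sum-of-squares ratio and
#' evaluates the upper F tail with \code{df_num} added regressors and
#' \code{df_den} residual degrees of freedom of the full model.
#'
#' @param gc nonnegative G-causality value.
#' @param df_num number of regressors added by the full model.
#' @param df_den residual degrees of freedom of the full model.
#' @return p-value in (0, 1]; \code{gc = 0} gives exactly 1.
#' @export
gc_significance <- function(gc, df_num, df_den) {
  if (gc < 0) stop("gc must be nonnegative", call. = FALSE)
  ratio <- exp(gc)
  gc_ftest(ratio, 1, df_num, df_den)
}

#' Prediction improvement from a G-causality value
#'
#' The per-cent reduction in one-step prediction-error variance obtained by
#' adding the cause's past to the model: \code{100 * exp(gc) - 100}.
#'
#' @param gc nonnegative G-causality value (log variance ratio).
#' @return prediction improvement in per cent.
#' @examples
#' prediction_improvement(log(2))  # 100
#' @export
prediction_improvement <- function(gc) {
  if (any(gc < 0)) stop("gc must be nonnegative; clip upstream", call. = FALSE)
  100 * expm1(gc)
}

#' All directed links of a multichannel series
#'
#' Convenience wrapper running \code{\link{gc_pairwise_conditional}} over
#' every ordered channel pair.
#'
#' @inheritParams gc_pairwise_conditional
#' @return data frame with one \code{gc_result} row per ordered pair.
#' @export
gc_all_links <- function(x, max_order = 20L, order = NULL, alpha = 0.05) {
  x <- as_channel_matrix(x)
  channels <- colnames(x)
  if (is.null(order)) {
    sc <- var_order_scan(x, as.integer(max_order))
    order <- which.min(sc$bic)
  }
  pairs <- expand.grid(from = channels, to = channels,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    gc_pairwise_conditional(x, pairs$from[i], pairs$to[i], order = order,
                            alpha = alpha)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
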