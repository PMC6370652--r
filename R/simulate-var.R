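#' Simulate a stable VAR process with analytic G-causality ground truth
#'
#' Exact simulation of a vector autoregression, plus closed-form
#' pairwise-conditional G-causality for every directed pair, computed from
#' the model's autocovariance sequence (long Yule-Walker approximation of
#' the restricted process). Used as the independent oracle for the Granger
#' estimators.
#'
#' @param coeffs coefficient array (k x k x p) or list of k x k lag
#'   matrices; \code{coeffs[i, j, l]} is the effect of channel j at lag l on
#'   channel i.
#' @param noise_cov innovation covariance (k x k, positive definite).
#' @param n number of observations to return.
#' @param seed integer seed (the simulation is deterministic given it).
#' @param burnin discarded initial samples.
#' @param yw_order order of the Yule-Walker approximation used for the
#'   restricted (cause-omitted) process in the analytic values.
#' @return list with \code{series} (n x k matrix), \code{analytic} (data
#'   frame \code{from}, \code{to}, \code{gc} for all ordered pairs),
#'   \code{coeffs}, \code{noise_cov}.
#' @examples
#' sim <- simulate_var(var_coeffs_unidirectional(0.9), diag(2), 1000, seed = 1)
#' subset(sim$analytic, from == "x" & to == "y")$gc  # log(1.81)
#' @export
simulate_var <- function(coeffs, noise_cov, n, seed, burnin = 500L,
                         yw_order = 200L) {
  A <- coerce_coeff_array(coeffs)
  k <- dim(A)[1L]
  p <- dim(A)[3L]
  channels <- dimnames(A)[[1L]] %||% paste0("ch", seq_len(k))
  noise_cov <- as.matrix(noise_cov)
  stopifnot(nrow(noise_cov) == k, ncol(noise_cov) == k)
  if (var_spectral_radius(A) >= 1) {
    stop("unstable VAR coefficients (companion spectral radius >= 1)",
         call. = FALSE)
  }
  L <- t(chol(noise_cov))

  n_tot <- n + burnin
  old_seed <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  e <- L %*% matrix(rnorm(k * n_tot), k, n_tot)
  x <- matrix(0, k, n_tot)
  for (t in seq_len(n_tot)) {
    acc <- e[, t]
    for (l in seq_len(min(p, t - 1L))) acc <- acc + A[, , l] %*% x[, t - l]
    x[, t] <- acc
  }
  series <- t(x[, (burnin + 1L):n_tot, drop = FALSE])
  colnames(series) <- channels

  pairs <- expand.grid(from = channels, to = channels,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  gamma <- var_autocov(A, noise_cov, max_lag = yw_order)
  pairs$gc <- vapply(seq_len(nrow(pairs)), function(i) {
    analytic_gc(A, noise_cov, pairs$from[i], pairs$to[i], gamma = gamma,
                yw_order = yw_order)
  }, numeric(1))
  rownames(pairs) <- NULL

  list(series = series, analytic = pairs, coeffs = A, noise_cov = noise_cov)
}

#' Coefficients of a canonical unidirectional bivariate VAR
#'
#' Channels \code{x} (white noise) and \code{y} with
#' \code{y_t = c * x_{t-1} + e_y}. With unit noises the analytic
#' G-causality of x on y is \code{log(1 + c^2)}.
#'
#' @param c lag-1 transfer coefficient.
#' @return 2 x 2 x 1 coefficient array with channels \code{x}, \code{y}.
#' @export
var_coeffs_unidirectional <- function(c = 0.9) {
  A <- array(0, dim = c(2, 2, 1),
             dimnames = list(c("x", "y"), c("x", "y"), NULL))
  A["y", "x", 1] <- c
  A
}

coerce_coeff_array <- function(coeffs) {
  if (is.list(coeffs)) {
    k <- nrow(coeffs[[1L]])
    A <- array(0, dim = c(k, k, length(coeffs)),
               dimnames = list(rownames(coeffs[[1L]]), colnames(coeffs[[1L]]),
                               NULL))
    for (l in seq_along(coeffs)) A[, , l] <- as.matrix(coeffs[[l]])
    coeffs <- A
  }
  if (length(dim(coeffs)) == 2L) coeffs <- array(coeffs, dim = c(dim(coeffs), 1L),
                                                 dimnames = c(dimnames(coeffs), list(NULL)))
  stopifnot(length(dim(coeffs)) == 3L, dim(coeffs)[1L] == dim(coeffs)[2L])
  if (is.null(dimnames(coeffs)[[1L]])) {
    dimnames(coeffs) <- list(paste0("ch", seq_len(dim(coeffs)[1L])),
                             paste0("ch", seq_len(dim(coeffs)[1L])), NULL)
  }
  coeffs
}

# autocovariance sequence Gamma(h) = E[x_t x_{t-h}'] for h = 0..max_lag,
# via the companion-form Lyapunov equation
var_autocov <- function(A, noise_cov, max_lag) {
  k <- dim(A)[1L]
  p <- dim(A)[3L]
  kp <- k * p
  F <- matrix(0, kp, kp)
  for (l in seq_len(p)) F[seq_len(k), (l - 1L) * k + seq_len(k)] <- A[, , l]
  if (p > 1L) F[(k + 1L):kp, seq_len(k * (p - 1L))] <- diag(k * (p - 1L))
  Q <- matrix(0, kp, kp)
  Q[seq_len(k), seq_len(k)] <- noise_cov
  vecG <- solve(diag(kp^2) - kronecker(F, F), as.vector(Q))
  Gc <- matrix(vecG, kp, kp)

  G <- vector("list", max_lag + 1L)
  for (h in 0:min(p - 1L, max_lag)) {
    G[[h + 1L]] <- Gc[seq_len(k), h * k + seq_len(k), drop = FALSE]
  }
  if (max_lag >= p) {
    for (h in p:max_lag) {
      acc <- matrix(0, k, k)
      for (l in seq_len(p)) {
        gl <- h - l
        Gl <- if (gl >= 0) G[[gl + 1L]] else t(G[[-gl + 1L]])
        acc <- acc + A[, , l] %*% Gl
      }
      G[[h + 1L]] <- acc
    }
  }
  G
}

# analytic pairwise-conditional GC: restricted process omits 'from';
# innovation variance of 'to' from a long Yule-Walker fit of the subprocess
analytic_gc <- function(A, noise_cov, from, to, gamma = NULL,
                        yw_order = 200L) {
  channels <- dimnames(A)[[1L]]
  from <- resolve_channel(from, channels)
  to <- resolve_channel(to, channels)
  if (is.null(gamma)) gamma <- var_autocov(A, noise_cov, yw_order)
  keep <- which(channels != from)
  m <- length(keep)
  q <- yw_order
  Gs <- lapply(gamma, function(g) g[keep, keep, drop = FALSE])
  Gblock <- function(h) if (h >= 0) Gs[[h + 1L]] else t(Gs[[-h + 1L]])

  R <- matrix(0, m * q, m * q)
  for (j in seq_len(q)) {
    for (i in seq_len(q)) {
      R[(j - 1L) * m + seq_len(m), (i - 1L) * m + seq_len(m)] <- Gblock(i - j)
    }
  }
  C <- do.call(cbind, lapply(seq_len(q), Gblock))  # [Gamma(1) ... Gamma(q)]
  Acoef <- t(solve(R, t(C)))                       # m x (m*q)
  V <- Gs[[1L]] - Acoef %*% t(C)
  to_sub <- match(to, channels[keep])
  v_r <- V[to_sub, to_sub]
  v_f <- noise_cov[match(to, channels), match(to, channels)]
  log(max(v_r, .Machine$double.eps) / v_f)
}
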