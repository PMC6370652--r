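#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx arima.sim coef complete.cases cor fft filter
#'   kruskal.test lm median na.omit pairwise.wilcox.test pf predict pt qnorm
#'   quantile rnorm runif sd setNames var wilcox.test rbinom
#' @importFrom utils head read.csv tail write.csv
#' @importFrom tools md5sum
NULL

# Coerce input to a numeric matrix with channel names.
as_channel_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("ch", seq_len(ncol(x)))
  if (anyNA(x)) stop("input series contain missing values", call. = FALSE)
  x
}

# Lagged design matrix, lag-major ordering (lag 1 of all channels, then lag 2,
# ...), so the first k*p columns form the order-p design. Rows are aligned to
# t = (max_lag + 1):n.
lag_design <- function(x, max_lag, include_lag0_of = NULL) {
  x <- as_channel_matrix(x)
  n <- nrow(x)
  k <- ncol(x)
  if (n <= max_lag + k) stop("series too short for requested lag order", call. = FALSE)
  rows <- (max_lag + 1L):n
  blocks <- lapply(seq_len(max_lag), function(l) {
    b <- x[rows - l, , drop = FALSE]
    colnames(b) <- paste0(colnames(x), ".l", l)
    b
  })
  out <- do.call(cbind, blocks)
  if (!is.null(include_lag0_of)) {
    b0 <- x[rows, include_lag0_of, drop = FALSE]
    colnames(b0) <- paste0(include_lag0_of, ".l0")
    out <- cbind(out, b0)
  }
  out
}

# channel-name/index resolution
resolve_channel <- function(ch, channels) {
  if (is.numeric(ch)) {
    ch <- as.integer(ch)
    if (ch < 1L || ch > length(channels)) stop("channel index out of range", call. = FALSE)
    return(channels[ch])
  }
  if (!ch %in% channels) {
    stop(sprintf("unknown channel '%s' (have: %s)", ch,
                 paste(channels, collapse = ", ")), call. = FALSE)
  }
  ch
}

# moving average with reflect padding; window length w samples (odd or even),
# output length equals input length
moving_average_reflect <- function(x, w) {
  n <- length(x)
  w <- max(1L, as.integer(w))
  if (w == 1L) return(x)
  left <- w %/% 2L
  right <- w - left - 1L
  refl <- function(k, from_start) {
    if (k == 0L) return(numeric(0))
    idx <- seq_len(k)
    if (from_start) {
      rev(x[pmin(n, idx + 1L)])
    } else {
      x[pmax(1L, n - idx)]
    }
  }
  xx <- c(refl(left, TRUE), x, refl(right, FALSE))
  cs <- cumsum(c(0, xx))
  (cs[(w + 1):(w + n)] - cs[seq_len(n)]) / w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
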