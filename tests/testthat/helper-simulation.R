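# shared fixtures, built once per test run

# short default supine recording with ground truth
fixture_recording <- local({
  cache <- NULL
  function(duration = 120, seed = 101, ...) {
    if (duration == 120 && length(list(...)) == 0 && seed == 101) {
      if (is.null(cache)) cache <<- simulate_subject(subject_spec(duration = 120,
                                                                  seed = 101))
      return(cache)
    }
    simulate_subject(subject_spec(duration = duration, seed = seed, ...))
  }
})

fixture_signal_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_signal_set(fixture_recording())
    cache
  }
})

fixture_beat_sequence <- function() {
  ss <- fixture_signal_set()
  build_beat_sequence(ss$r_peaks, ss$z_smooth, ss$phases, ss$insp_onsets, 250)
}

# bivariate additive-noise pair: lagged x -> y with selectable noise law
sim_anm_pair <- function(n, seed, noise = c("uniform", "gaussian"),
                         lagged = TRUE) {
  noise <- match.arg(noise)
  set.seed(seed)
  rgen <- if (noise == "uniform") function(n) runif(n, -1, 1) else
    function(n) rnorm(n, 0, sqrt(1 / 3))
  u <- rgen(n)
  v <- rgen(n)
  x <- numeric(n)
  y <- numeric(n)
  if (lagged) {
    for (t in 2:n) {
      x[t] <- 0.5 * x[t - 1] + u[t]
      y[t] <- 0.5 * y[t - 1] + 0.8 * x[t - 1] + v[t]
    }
  } else {
    x <- u
    y <- x + 0.5 * v
  }
  list(x = x, y = y)
}

# small bank of stable VARs with known structure, used across GC tests
var_bank <- function() {
  A2 <- array(0, dim = c(2, 2, 2), dimnames = list(c("x", "y"), c("x", "y"), NULL))
  A2["x", "x", 1] <- 0.55
  A2["y", "y", 1] <- 0.35
  A2["y", "x", 1] <- 0.4
  A2["y", "x", 2] <- -0.3
  A2["x", "x", 2] <- -0.2
  list(
    unidir = list(coeffs = var_coeffs_unidirectional(0.9), noise = diag(2)),
    lag2 = list(coeffs = A2, noise = diag(2)),
    corr_noise = list(coeffs = A2, noise = matrix(c(1, 0.4, 0.4, 1), 2))
  )
}
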