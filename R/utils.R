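# Internal numeric helpers shared across modules.

#' Centered moving average with edge truncation
#'
#' The window shrinks at the series boundaries so that the output has the same
#' length as the input and no samples are padded in.
#'
#' @param x numeric vector.
#' @param n_window window length in samples; forced to the nearest odd integer
#'   so the window is symmetric around each sample.
#' @return numeric vector, same length as `x`.
#' @keywords internal
#' @noRd
moving_average <- function(x, n_window) {
  n <- length(x)
  w <- max(1L, as.integer(n_window))
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  if (half == 0L || n == 0L) return(as.numeric(x))
  cs <- cumsum(c(0, x))
  idx <- seq_len(n)
  i1 <- pmax(1L, idx - half)
  i2 <- pmin(n, idx + half)
  (cs[i2 + 1L] - cs[i1]) / (i2 - i1 + 1L)
}

# Odd window length in samples for a duration in seconds.
odd_window <- function(dur_s, fs) 2L * as.integer(floor(dur_s * fs / 2)) + 1L

#' FFT-based linear convolution, central ("same") segment
#'
#' Supports complex kernels; used for the Morlet transform.
#' @keywords internal
#' @noRd
convolve_same <- function(x, kernel) {
  n <- length(x)
  m <- length(kernel)
  L <- stats::nextn(n + m - 1L, 2L)
  X <- stats::fft(c(x, rep(0, L - n)))
  K <- stats::fft(c(kernel, rep(0, L - m)))
  y <- stats::fft(X * K, inverse = TRUE) / L
  off <- (m - 1L) %/% 2L
  y[(off + 1L):(off + n)]
}

#' Analytic signal via the frequency-domain Hilbert transform
#' @keywords internal
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1L) h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Run a block with a locally seeded RNG, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Half-open [start_s, end_s) interval -> 1-based sample index range at fs.
interval_to_samples <- function(start_s, end_s, fs, n_samples) {
  i1 <- as.integer(floor(start_s * fs + 1e-9)) + 1L
  i2 <- as.integer(ceiling(end_s * fs - 1e-9))
  c(max(1L, i1), min(n_samples, i2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
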