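#' Normalized sinc function
#' @noRd
sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

#' Windowed-sinc fractional-delay kernel
#'
#' Returns an FIR kernel of `n_taps + 1` coefficients whose group delay is
#' `n_taps / 2 + delay` samples. The Hann window is centred on the (shifted)
#' sinc peak so sub-sample shifts keep a flat passband.
#'
#' @param delay delay in samples; any real value with `|delay| < n_taps / 2`.
#' @param n_taps kernel order (even integer); default 64.
#' @return numeric vector of length `n_taps + 1`.
#' @keywords internal
#' @export
delay_kernel <- function(delay, n_taps = 64) {
  stopifnot(n_taps %% 2 == 0, abs(delay) < n_taps / 2)
  centre <- n_taps / 2 + delay
  k <- 0:n_taps
  u <- k - centre
  w <- ifelse(abs(u) < n_taps / 2, 0.5 * (1 + cos(2 * pi * u / n_taps)), 0)
  sinc(u) * w
}

#' Delay a signal by a fractional number of samples
#'
#' Splits the delay into an integer shift and a sub-sample remainder; the
#' remainder is realized with a windowed-sinc interpolation kernel. Output has
#' the same length as the input (content shifted, edges zero-padded).
#'
#' @param x numeric signal.
#' @param delay delay in samples (positive = later); may be negative.
#' @param n_taps fractional-delay kernel order (default 64).
#' @return numeric vector, `length(x)`.
#' @export
#' @examples
#' x <- sin(2 * pi * 5 * seq(0, 1, length.out = 200))
#' y <- fractional_delay(x, 2.5)
fractional_delay <- function(x, delay, n_taps = 64) {
  m <- round(delay)
  f <- delay - m
  if (f != 0) {
    h <- delay_kernel(f, n_taps)
    g <- n_taps / 2
    y <- fft_convolve(x, h)
    x <- y[(g + 1):(g + length(x))]
  }
  n <- length(x)
  if (m > 0) {
    x <- c(rep(0, m), x[seq_len(n - m)])
  } else if (m < 0) {
    x <- c(x[(1 - m):n], rep(0, -m))
  }
  x
}

#' Linear convolution via FFT
#' @noRd
fft_convolve <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n, 2)
  X <- fft(c(x, rep(0, nfft - length(x))))
  H <- fft(c(h, rep(0, nfft - length(h))))
  Re(fft(X * H, inverse = TRUE))[seq_len(n)] / nfft
}

#' Smallest 5-smooth integer >= n (mixed-radix FFT stays O(n log n))
#' @noRd
good_fft_length <- function(n) {
  m <- n
  repeat {
    k <- m
    for (p in c(2, 3, 5)) while (k %% p == 0) k <- k / p
    if (k == 1) {
      return(m)
    }
    m <- m + 1
  }
}

#' Analytic signal via the FFT half-spectrum method
#'
#' Signals whose length has a large prime factor are zero-padded to the next
#' 5-smooth length before the transform and truncated afterwards; the
#' padding perturbs only the edges (the Hilbert kernel decays as 1/t), which
#' downstream cue extraction trims anyway.
#'
#' @param x real numeric signal, length >= 8, all finite.
#' @return complex vector: `x + i * H(x)` where `H` is the Hilbert transform.
#' @keywords internal
#' @export
analytic_signal <- function(x) {
  if (length(x) < 8) stop("signal too short for analytic-signal extraction")
  if (!all(is.finite(x))) stop("non-finite samples in signal")
  n0 <- length(x)
  n <- good_fft_length(n0)
  if (n > n0) x <- c(x, rep(0, n - n0))
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(fft(x) * h, inverse = TRUE) / n
  z[seq_len(n0)]
}

#' Instantaneous phase and amplitude of a signal
#'
#' Extracts the angle and magnitude of the analytic signal (Hilbert-transform
#' envelope and phase).
#'
#' @param x real numeric signal, length >= 8.
#' @return a list with numeric vectors `phase` (radians, in (-pi, pi\]) and
#'   `amplitude`, both of `length(x)`.
#' @export
#' @examples
#' fs <- 8000
#' x <- cos(2 * pi * 440 * seq(0, 0.1, by = 1 / fs))
#' pa <- instantaneous_phase_amplitude(x)
instantaneous_phase_amplitude <- function(x) {
  z <- analytic_signal(x)
  list(phase = Arg(z), amplitude = Mod(z))
}

#' Wrap angles to the principal interval (-pi, pi]
#' @noRd
wrap_angle <- function(a) {
  w <- atan2(sin(a), cos(a))
  ifelse(w == -pi, pi, w)
}

#' Interior slice of a signal after trimming a fraction at both ends
#' @noRd
trim_edges <- function(n, discard_edges) {
  stopifnot(discard_edges >= 0, discard_edges <= 0.4)
  k <- floor(n * discard_edges)
  if (n - 2 * k < 1) stop("edge trimming leaves no samples")
  (k + 1):(n - k)
}

#' Seeded Gaussian white-noise probe
#' @noRd
white_noise <- function(n, seed = NULL) {
  if (!is.null(seed)) {
    return(withr_seed(seed, rnorm(n)))
  }
  rnorm(n)
}

#' Evaluate an expression under a local RNG seed, restoring the global state
#' @noRd
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
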