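#' Generate colored (power-law) noise by spectral synthesis
#'
#' Synthesises a series whose power spectrum falls off as a power of
#' frequency, following the widely used spectral-synthesis recipe of
#' Little and colleagues (`powernoise`): the Fourier amplitude at index
#' j (j = 1, ..., n/2 - 1) is set to `(j + 1)^(-alpha/2)`, the phase is
#' drawn uniformly at random, the DC component is zero, the Nyquist
#' component is real with amplitude `(n/2 + 1)^(-alpha)`, and the series
#' is the real part of the inverse transform, normalized to mean 0 and
#' unit (population) standard deviation.  Odd lengths are synthesised at
#' the next even length and truncated by one sample.
#'
#' The one-bin offset in the amplitude rule (`j + 1` rather than `j`)
#' slightly flattens the lowest frequencies relative to a pure power
#' law.  It is retained deliberately: it is what the reference recipe
#' does, and it is what makes finite-length calibration constants (such
#' as the mean Whittle value near 0.43 for alpha = 1 at movie-like
#' lengths) come out where they do.  See the methods vignette.
#'
#' @param n series length, at least 8.
#' @param alpha intended spectral exponent in `1/f^alpha`, in \[0, 3\].
#'   0 gives white noise, 1 pink (fractal) noise, 2 brown noise.
#' @param seed optional integer; when given, the draw is deterministic
#'   and the caller's RNG stream is left untouched.
#' @return a normalized [event_series()] with attribute `intended_alpha`.
#' @examples
#' x <- colored_noise(1024, alpha = 1, seed = 1)
#' @seealso [arfima_sim()] for an independent time-domain generator.
#' @export
colored_noise <- function(n, alpha, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 8) {
    stop("'n' must be a single length >= 8", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 3) {
    stop("'alpha' must lie in [0, 3]", call. = FALSE)
  }
  n <- as.integer(n)
  x <- with_seed(seed, {
    ne <- n + (n %% 2L)            # synthesise at even length
    n2 <- ne %/% 2L - 1L
    amp <- (2:(n2 + 1L))^(-alpha / 2)
    phase <- runif(n2, -pi, pi)
    half <- amp * exp(1i * phase)
    spec <- c(0 + 0i,                      # DC removed (series is demeaned)
              half,
              (n2 + 2L)^(-alpha) + 0i,     # real Nyquist component
              Conj(rev(half)))
    Re(fft(spec, inverse = TRUE))[seq_len(n)] / ne
  })
  out <- normalize_series(x)
  out <- event_series(out, dimension = "synthetic")
  attr(out, "intended_alpha") <- alpha
  out
}

#' Simulate a fractionally integrated (ARFIMA(0, d, 0)) series
#'
#' Fractionally integrates seeded Gaussian white noise with the
#' truncated binomial recursion (the same kernel used by the exact local
#' Whittle criterion, applied with -d), then normalizes.  This is the
#' package's independent oracle generator for parameter-recovery tests:
#' its memory parameter is d by construction, with no spectral-synthesis
#' conventions involved.
#'
#' @param n series length, at least 8.
#' @param d memory parameter in (-0.5, 1.5).  d = 0 returns normalized
#'   white noise; d = 1 a random walk (cumulative sum).
#' @param seed optional integer seed.
#' @return a normalized [event_series()] with attribute `intended_d`.
#' @export
arfima_sim <- function(n, d, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 8) {
    stop("'n' must be a single length >= 8", call. = FALSE)
  }
  if (!is.numeric(d) || length(d) != 1L || d <= -0.5 || d >= 1.5) {
    stop("'d' must lie in (-0.5, 1.5)", call. = FALSE)
  }
  n <- as.integer(n)
  x <- with_seed(seed, {
    eps <- rnorm(n)
    fractional_difference(eps, -d)
  })
  out <- normalize_series(x)
  out <- event_series(out, dimension = "synthetic")
  attr(out, "intended_d") <- d
  out
}
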