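#' Fit the fractal structure of a film event series
#'
#' The front door of the package for a single series.  The series is
#' normalized (mean 0, population sd 1) and both measures of fractal
#' structure are computed: the sliding-window spectral slope from the
#' hybrid white + colored model ([windowed_power()] + [fit_hybrid()]),
#' and the exact local Whittle memory parameter ([local_whittle()]).
#'
#' The slope requires at least `min_shots` events (default 512, the
#' usual eligibility rule for movie shot vectors); shorter series get
#' `slope = NULL` and `slope_excluded = TRUE` rather than an error, so
#' corpus runs can proceed.  The Whittle estimate is computed whenever
#' `n >= min_whittle`.
#'
#' @param x numeric vector or [event_series()].
#' @param estimator `"both"` (default), `"slope"`, or `"whittle"`.
#' @param min_shots slope eligibility threshold (default 512).
#' @param max_exponent largest window-length power of two (default 8).
#' @param bandwidth_exponent Whittle bandwidth rule (default 0.65).
#' @param min_whittle shortest series for the Whittle step (default 32).
#' @return object of class `"fractal_fit"` with components `slope`
#'   (a `"hybrid_fit"` or NULL), `whittle` (a `"whittle_fit"` or NULL),
#'   `spectrum`, `n`, `series` (the normalized series), and flags.
#' @examples
#' fit <- fractal_fit(colored_noise(1024, 1, seed = 7))
#' fit
#' coef(fit)
#' @export
fractal_fit <- function(x, estimator = c("both", "slope", "whittle"),
                        min_shots = 512L, max_exponent = 8L,
                        bandwidth_exponent = 0.65, min_whittle = 32L) {
  estimator <- match.arg(estimator)
  v <- normalize_series(x)
  n <- length(v)
  slope <- NULL; spectrum <- NULL; whittle <- NULL
  slope_excluded <- FALSE
  if (estimator %in% c("both", "slope")) {
    if (n >= max(min_shots, 2L^max_exponent)) {
      spectrum <- windowed_power(v, max_exponent = max_exponent,
                                 min_length = min_shots)
      slope <- fit_hybrid(spectrum)
    } else {
      slope_excluded <- TRUE
      message(sprintf(
        "series excluded from slope analysis (n = %d < %d)", n, min_shots))
    }
  }
  if (estimator %in% c("both", "whittle")) {
    whittle <- local_whittle(v, bandwidth_exponent = bandwidth_exponent,
                             min_length = min_whittle)
  }
  structure(list(slope = slope, whittle = whittle, spectrum = spectrum,
                 n = n, series = v, slope_excluded = slope_excluded,
                 movie_id = attr(x, "movie_id"),
                 year = attr(x, "year"),
                 dimension = attr(x, "dimension"),
                 call = match.call()),
            class = "fractal_fit")
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat("Fractal structure fit\n")
  if (!is.null(x$movie_id) && !is.na(x$movie_id)) {
    cat(sprintf("  series: %s (%s, %s), n = %d\n",
                x$movie_id, x$dimension, x$year, x$n))
  } else {
    cat(sprintf("  n = %d\n", x$n))
  }
  if (!is.null(x$slope)) {
    cat(sprintf("  spectral slope alpha = %.3f (rmsd %.3f)\n",
                x$slope$alpha, x$slope$rmsd_log))
  } else if (x$slope_excluded) {
    cat("  spectral slope: excluded (series too short)\n")
  }
  if (!is.null(x$whittle)) {
    cat(sprintf("  Whittle d = %.3f (m = %d)\n", x$whittle$d, x$whittle$m))
  }
  invisible(x)
}

#' @export
summary.fractal_fit <- function(object, ...) {
  out <- list(n = object$n,
              alpha = if (is.null(object$slope)) NA_real_ else object$slope$alpha,
              colored_scale = if (is.null(object$slope)) NA_real_ else object$slope$colored_scale,
              white_level = if (is.null(object$slope)) NA_real_ else object$slope$white_level,
              rmsd_log = if (is.null(object$slope)) NA_real_ else object$slope$rmsd_log,
              d = if (is.null(object$whittle)) NA_real_ else object$whittle$d,
              m = if (is.null(object$whittle)) NA_integer_ else object$whittle$m,
              slope_excluded = object$slope_excluded)
  class(out) <- "summary.fractal_fit"
  out
}

#' @export
print.summary.fractal_fit <- function(x, ...) {
  cat(sprintf("n = %d | alpha = %.3f | d = %.3f | rmsd = %.3f\n",
              x$n, x$alpha, x$d, x$rmsd_log))
  invisible(x)
}

#' @export
coef.fractal_fit <- function(object, ...) {
  c(alpha = if (is.null(object$slope)) NA_real_ else object$slope$alpha,
    d = if (is.null(object$whittle)) NA_real_ else object$whittle$d)
}

#' Residuals of the hybrid spectral fit
#'
#' Log10 deviations of mean window power from the fitted hybrid model,
#' one per window length.
#' @param object a [fractal_fit()] result with a slope component.
#' @param ... unused.
#' @export
residuals.fractal_fit <- function(object, ...) {
  if (is.null(object$slope)) stop("no spectral fit in this object", call. = FALSE)
  log10(object$slope$spectrum$mean_power) - log10(object$slope$fitted)
}

#' Model power predicted at given wavelengths
#'
#' @param object a [fractal_fit()] result with a slope component.
#' @param wavelengths wavelengths (window lengths) at which to evaluate
#'   the fitted hybrid model; defaults to the fitted ones.
#' @param ... unused.
#' @export
predict.fractal_fit <- function(object, wavelengths = NULL, ...) {
  if (is.null(object$slope)) stop("no spectral fit in this object", call. = FALSE)
  if (is.null(wavelengths)) wavelengths <- object$slope$spectrum$window_lengths
  s <- object$slope
  s$colored_scale * wavelengths^s$alpha + s$white_level
}

#' Simulate series matching a fitted fractal structure
#'
#' Draws colored-noise series at the fitted spectral exponent (or, when
#' only the Whittle estimate is available, at `2.32 * d`, the grand-mean
#' rescaling between the two measures) and the fitted series length.
#'
#' @param object a [fractal_fit()] result.
#' @param nsim number of series.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of [event_series()] of length `nsim`.
#' @export
simulate.fractal_fit <- function(object, nsim = 1, seed = NULL, ...) {
  alpha <- if (!is.null(object$slope)) object$slope$alpha
           else min(3, max(0, 2.32 * object$whittle$d))
  seeds <- spawn_seeds(if (is.null(seed)) sample.int(2^30, 1) else seed, nsim)
  lapply(seeds, function(s) colored_noise(object$n, alpha, seed = s))
}

#' Plot a fitted windowed spectrum
#'
#' Log-log plot of mean window power against wavelength, with the
#' fitted hybrid curve.  Following the field's convention the
#' wavelength axis descends (longest window leftmost).
#'
#' @param x a [fractal_fit()] result with a slope component.
#' @param ... passed to [plot()].
#' @export
plot.fractal_fit <- function(x, ...) {
  if (is.null(x$slope)) stop("no spectral fit to plot", call. = FALSE)
  sp <- x$slope$spectrum
  L <- sp$window_lengths
  lx <- -log10(L)                       # descending wavelength axis
  plot(lx, log10(sp$mean_power), xaxt = "n",
       xlab = "wavelength (events)", ylab = "log10 mean power",
       pch = 16, ...)
  axis(1, at = -log10(L), labels = L)
  lines(lx, log10(x$slope$fitted), col = "red3", lwd = 2)
  legend("topleft", bty = "n",
         legend = sprintf("alpha = %.2f, d = %.2f", x$slope$alpha,
                          if (is.null(x$whittle)) NA else x$whittle$d))
  invisible(x)
}
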