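#' Sliding-window power spectrum of an event series
#'
#' For each window length L = 2, 4, ..., `2^max_exponent`, a window
#' slides along the normalized series in steps of one event; in each
#' window the power of the best-fitting sinusoid at the window's
#' fundamental wavelength is computed (the squared modulus of the
#' window's first DFT coefficient divided by L), and the mean over all
#' `n - L + 1` windows is recorded.  Dividing by L makes white noise
#' flat across window lengths; any L-independent rescaling is
#' slope-neutral.  Windows never wrap.
#'
#' @param x numeric vector or [event_series()].  Unnormalized input is
#'   normalized with a warning.
#' @param max_exponent largest power of two used as a window length
#'   (default 8, i.e. wavelengths up to 256 events).
#' @param min_length shortest admissible series; default
#'   `2 * 2^max_exponent` (512 for the default truncation), mirroring
#'   the eligibility rule used for movie shot vectors.
#' @return object of class `"windowed_spectrum"`: `window_lengths`,
#'   `mean_power`, `n_windows`, `n`.
#' @examples
#' windowed_power(colored_noise(1024, 1, seed = 1))
#' @export
windowed_power <- function(x, max_exponent = 8L,
                           min_length = 2L * 2L^max_exponent) {
  v <- as.numeric(x)
  n <- length(v)
  if (max_exponent < 1L) stop("'max_exponent' must be >= 1", call. = FALSE)
  if (n < min_length || n < 2L^max_exponent) {
    stop(sprintf("series too short for windowed power (n = %d < %d)",
                 n, max(min_length, 2L^max_exponent)), call. = FALSE)
  }
  if (sqrt(mean((v - mean(v))^2)) <= 0) {
    stop("cannot analyze a degenerate (constant) series", call. = FALSE)
  }
  if (!is_normalized(v)) {
    warning("input was not normalized; normalizing (mean 0, population sd 1)",
            call. = FALSE)
    v <- normalize_series(v)
  }
  lengths <- 2L^seq_len(max_exponent)
  mean_power <- numeric(length(lengths))
  n_windows <- integer(length(lengths))
  for (k in seq_along(lengths)) {
    L <- lengths[k]
    th <- 2 * pi * (0:(L - 1L)) / L
    # filter coefficient j multiplies x[t - j + 1]; reversing aligns the
    # complex exponential with window position so that y[t] is the first
    # DFT coefficient of x[(t - L + 1):t]
    re <- stats::filter(v, rev(cos(th)), sides = 1)
    im <- stats::filter(v, rev(-sin(th)), sides = 1)
    pw <- (re^2 + im^2)[L:n] / L
    mean_power[k] <- mean(pw)
    n_windows[k] <- n - L + 1L
  }
  structure(list(window_lengths = lengths, mean_power = mean_power,
                 n_windows = n_windows, n = n),
            class = "windowed_spectrum")
}

#' @export
print.windowed_spectrum <- function(x, ...) {
  cat(sprintf("<windowed_spectrum> n = %d, wavelengths %s\n",
              x$n, paste(x$window_lengths, collapse = ", ")))
  print(data.frame(wavelength = x$window_lengths,
                   mean_power = signif(x$mean_power, 4),
                   windows = x$n_windows), row.names = FALSE)
  invisible(x)
}

#' Fit the hybrid white + colored noise model to a windowed spectrum
#'
#' Models mean window power as `colored_scale * L^alpha + white_level`
#' and minimizes the sum of squared deviations in log10 power over the
#' window lengths L, with `alpha` bounded to \[0, 3\] and both scales
#' nonnegative.  The wavelength L is the regressor, so `alpha` is the
#' exponent on wavelength — identical to the exponent in `1/f^alpha`.
#' Fitting uses an alpha grid (step 0.05) with the two scales solved by
#' least squares at each grid point, followed by bounded quasi-Newton
#' polish from the best starts; ties in loss break toward the smaller
#' alpha.
#'
#' Because the colored exponent is unidentified when its scale is zero,
#' a flat spectrum would otherwise receive an arbitrary alpha.  The fit
#' therefore keeps the colored component only when it improves on the
#' white-only model by a conservative F test (2 extra parameters,
#' alpha level 0.01); otherwise the spectrum is reported as white
#' (`alpha = 0`, `colored_scale = 0`).
#'
#' @param spectrum a [windowed_power()] result.
#' @return object of class `"hybrid_fit"`: `alpha`, `colored_scale`,
#'   `white_level`, `rmsd_log` (root-mean-square deviation of the log10
#'   power fit), `fitted`, and the input `spectrum`.
#' @examples
#' sp <- windowed_power(colored_noise(1024, 1, seed = 1))
#' fit_hybrid(sp)
#' @export
fit_hybrid <- function(spectrum) {
  if (!inherits(spectrum, "windowed_spectrum")) {
    stop("'spectrum' must be a windowed_spectrum", call. = FALSE)
  }
  P <- spectrum$mean_power
  L <- as.numeric(spectrum$window_lengths)
  if (!all(is.finite(P)) || any(P <= 0)) {
    stop("spectrum values must be positive and finite", call. = FALSE)
  }
  lP <- log10(P)
  k <- length(P)
  # white-only reference fit
  w0 <- mean(lP)
  loss_white <- sum((lP - w0)^2)

  loss_fun <- function(par) {                 # par = (alpha, log c, log w)
    sum((lP - log10(exp(par[2]) * L^par[1] + exp(par[3])))^2)
  }
  # inner least squares for the two scales at fixed alpha (power scale,
  # clipped to nonnegative) — used to rank grid starts cheaply
  inner <- function(a) {
    cf <- tryCatch(qr.solve(cbind(L^a, 1), P), error = function(e) c(NA, NA))
    if (any(!is.finite(cf))) return(list(loss = Inf, cf = c(1e-12, 1e-12)))
    cf <- pmax(cf, 1e-12)
    list(loss = sum((lP - log10(cf[1] * L^a + cf[2]))^2), cf = cf)
  }
  a_grid <- seq(0, 3, by = 0.05)
  grid_fits <- lapply(a_grid, inner)
  ord <- order(vapply(grid_fits, `[[`, numeric(1), "loss"))
  starts <- head(ord, 4L)
  cand <- lapply(starts, function(i) {
    cf <- grid_fits[[i]]$cf
    optim(c(a_grid[i], log(cf[1]), log(cf[2])), loss_fun,
          method = "L-BFGS-B",
          lower = c(0, -60, -60), upper = c(3, 60, 60))
  })
  losses <- vapply(cand, `[[`, numeric(1), "value")
  alphas <- vapply(cand, function(o) o$par[1], numeric(1))
  loss_min <- min(losses)
  pick <- which(losses <= loss_min + 1e-9)
  best <- cand[[pick[which.min(alphas[pick])]]]

  alpha <- best$par[1]
  colored_scale <- exp(best$par[2])
  white_level <- exp(best$par[3])
  loss <- best$value

  # parsimony gate: colored component must beat white-only decisively
  f_stat <- ((loss_white - loss) / 2) / (loss / (k - 3) + 1e-300)
  if (f_stat <= qf(0.99, 2, k - 3)) {
    alpha <- 0
    colored_scale <- 0
    white_level <- 10^w0
    loss <- loss_white
  }
  fitted <- colored_scale * L^alpha + white_level
  structure(list(alpha = alpha, colored_scale = colored_scale,
                 white_level = white_level,
                 rmsd_log = sqrt(loss / k),
                 fitted = fitted, spectrum = spectrum),
            class = "hybrid_fit")
}

#' @export
print.hybrid_fit <- function(x, ...) {
  cat(sprintf("Hybrid white + 1/f^alpha fit: alpha = %.3f\n", x$alpha))
  cat(sprintf("  colored scale %.4g, white level %.4g, rmsd(log10) %.4f\n",
              x$colored_scale, x$white_level, x$rmsd_log))
  invisible(x)
}

#' @export
coef.hybrid_fit <- function(object, ...) {
  c(alpha = object$alpha, colored_scale = object$colored_scale,
    white_level = object$white_level)
}
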