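#' Calibration grid: estimators across intended alpha and series length
#'
#' Generates colored noise at every combination of intended spectral
#' exponent and vector length, runs both the sliding-window hybrid
#' slope and the exact local Whittle estimator on each replicate, and
#' summarises each cell by the mean and standard deviation of both
#' estimates.  The defaults are the standard calibration conditions for
#' movie-like series: alphas 0 to 2 in steps of 0.25 and lengths 512,
#' 768, 1024, 1536, 2048, 3072.
#'
#' Grand means are computed over all cells (cells weighted equally, and
#' including the alpha = 0 cells: the ratio of grand means is stable
#' where per-cell ratios are not).  `whittle_to_slope_ratio` is the
#' grand-mean Whittle divided by the grand-mean slope, and
#' `rescale_factor` its reciprocal — the multiplier that equalizes the
#' two grand means.
#'
#' @param alphas intended spectral exponents.
#' @param lengths vector lengths; each must satisfy the slope
#'   eligibility rule (at least 512 when slope estimation is enabled).
#' @param reps replicates per cell (default 1000; 100 gives
#'   rep-robust grand means at a fraction of the cost).
#' @param seed master seed; per-cell seeds are spawned from it so the
#'   grid is reproducible.
#' @param bandwidth_exponent Whittle bandwidth rule.
#' @param estimators run `"both"` (default) or `"whittle"` only.
#' @return object of class `"alpha_length_grid"`: `cells` (one row per
#'   cell), `grand_slope_mean`, `grand_whittle_mean`,
#'   `whittle_to_slope_ratio`, `rescale_factor`, `reps`, `n_failed`.
#' @examples
#' g <- alpha_length_grid(alphas = c(0, 1), lengths = c(512, 1024),
#'                        reps = 5, seed = 1)
#' g$cells
#' @export
alpha_length_grid <- function(alphas = seq(0, 2, by = 0.25),
                              lengths = c(512, 768, 1024, 1536, 2048, 3072),
                              reps = 1000L, seed = NULL,
                              bandwidth_exponent = 0.65,
                              estimators = c("both", "whittle")) {
  estimators <- match.arg(estimators)
  if (length(alphas) < 1L) stop("'alphas' must be non-empty", call. = FALSE)
  if (estimators == "both" && any(lengths < 512)) {
    stop("lengths below 512 are ineligible for slope estimation",
         call. = FALSE)
  }
  cells <- expand.grid(intended_alpha = alphas, length = lengths,
                       KEEP.OUT.ATTRS = FALSE)
  cell_seeds <- spawn_seeds(if (is.null(seed)) sample.int(2^30, 1) else seed,
                            nrow(cells))
  res <- vector("list", nrow(cells))
  n_failed <- 0L
  for (ci in seq_len(nrow(cells))) {
    a <- cells$intended_alpha[ci]
    n <- cells$length[ci]
    rs <- spawn_seeds(cell_seeds[ci], reps)
    sl <- wh <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      x <- colored_noise(n, a, seed = rs[r])
      ok <- tryCatch({
        if (estimators == "both") sl[r] <- fit_hybrid(windowed_power(x))$alpha
        wh[r] <- local_whittle(x, bandwidth_exponent = bandwidth_exponent)$d
        TRUE
      }, error = function(e) FALSE)
      if (!ok) n_failed <- n_failed + 1L
    }
    res[[ci]] <- data.frame(
      intended_alpha = a, length = n, reps = sum(!is.na(wh)),
      slope_mean = mean(sl, na.rm = TRUE), slope_sd = sd(sl[!is.na(sl)]),
      whittle_mean = mean(wh, na.rm = TRUE), whittle_sd = sd(wh[!is.na(wh)]))
  }
  cells <- do.call(rbind, res)
  grand_slope <- mean(cells$slope_mean)
  grand_whittle <- mean(cells$whittle_mean)
  structure(list(cells = cells,
                 grand_slope_mean = grand_slope,
                 grand_whittle_mean = grand_whittle,
                 whittle_to_slope_ratio = grand_whittle / grand_slope,
                 rescale_factor = grand_slope / grand_whittle,
                 reps = reps, n_failed = n_failed,
                 bandwidth_exponent = bandwidth_exponent),
            class = "alpha_length_grid")
}

#' @export
print.alpha_length_grid <- function(x, ...) {
  cat(sprintf("alpha x length calibration grid: %d cells x %d reps\n",
              nrow(x$cells), x$reps))
  cat(sprintf("  grand-mean slope   %.4f\n", x$grand_slope_mean))
  cat(sprintf("  grand-mean Whittle %.4f\n", x$grand_whittle_mean))
  cat(sprintf("  Whittle/slope ratio %.4f  (rescale factor %.3f)\n",
              x$whittle_to_slope_ratio, x$rescale_factor))
  if (x$n_failed > 0) cat(sprintf("  %d replicate(s) failed\n", x$n_failed))
  invisible(x)
}

#' Vector-doubling experiment
#'
#' Doubles each series end to end — either by plain concatenation or as
#' an enantiomorph (the series followed by its reversal, which avoids
#' introducing an exact period) — and runs both estimators on the
#' original and the doubled vector.  If measured fractal structure were
#' an artifact of vector length, doubling would inflate it; near-equal
#' values show it is not.
#'
#' @param series_list list of numeric vectors or [event_series()].
#' @param mode `"concat"` or `"enantiomorph"`.
#' @param min_shots slope eligibility rule applied to the original
#'   series (default 512); ineligible series get NA slopes.
#' @param bandwidth_exponent Whittle bandwidth rule.
#' @return data.frame with one row per series: `n`, `slope_orig`,
#'   `slope_doubled`, `whittle_orig`, `whittle_doubled`.
#' @export
doubling_experiment <- function(series_list,
                                mode = c("concat", "enantiomorph"),
                                min_shots = 512L,
                                bandwidth_exponent = 0.65) {
  mode <- match.arg(mode)
  if (!is.list(series_list)) series_list <- list(series_list)
  rows <- lapply(series_list, function(x) {
    v <- as.numeric(x)
    dbl <- if (mode == "concat") c(v, v) else c(v, rev(v))
    slope_o <- slope_d <- NA_real_
    if (length(v) >= min_shots) {
      slope_o <- tryCatch(
        fit_hybrid(windowed_power(normalize_series(v)))$alpha,
        error = function(e) NA_real_)
      slope_d <- tryCatch(
        fit_hybrid(windowed_power(normalize_series(dbl)))$alpha,
        error = function(e) NA_real_)
    }
    w_o <- tryCatch(local_whittle(v, bandwidth_exponent)$d,
                    error = function(e) NA_real_)
    w_d <- tryCatch(local_whittle(dbl, bandwidth_exponent)$d,
                    error = function(e) NA_real_)
    data.frame(n = length(v), slope_orig = slope_o, slope_doubled = slope_d,
               whittle_orig = w_o, whittle_doubled = w_d)
  })
  do.call(rbind, rows)
}

#' Simulation-based standard error of a Whittle estimate
#'
#' For a measured memory parameter `d_hat` and a series length, draws
#' `reps` colored-noise series at the intended exponent
#' `alpha = rescale * d_hat` (2.32 being the grand-mean rescaling
#' between Whittle and slope measures) and returns the standard
#' deviation of the Whittle estimates.  This is how error bars are put
#' on Whittle values from short vectors, such as the 35-215 scene
#' counts of segmented movies.
#'
#' @param d_hat measured memory parameter, in \[0, 1\].
#' @param length series length (>= 16).
#' @param reps simulation replicates (default 1000).
#' @param seed optional master seed.
#' @param rescale d-to-alpha conversion factor (default 2.32).
#' @param bandwidth_exponent Whittle bandwidth rule.
#' @return the standard deviation (a single number).
#' @export
whittle_sd_calibration <- function(d_hat, length, reps = 1000L, seed = NULL,
                                   rescale = 2.32,
                                   bandwidth_exponent = 0.65) {
  if (!is.numeric(d_hat) || length(d_hat) != 1L || d_hat < 0 || d_hat > 1) {
    stop("'d_hat' must be a single value in [0, 1]", call. = FALSE)
  }
  if (length < 16L) stop("'length' must be >= 16", call. = FALSE)
  alpha <- min(3, rescale * d_hat)
  seeds <- spawn_seeds(if (is.null(seed)) sample.int(2^30, 1) else seed, reps)
  est <- vapply(seeds, function(s) {
    local_whittle(colored_noise(length, alpha, seed = s),
                  bandwidth_exponent = bandwidth_exponent,
                  min_length = 16L, warn = FALSE)$d
  }, numeric(1))
  sd(est)
}

#' Analytic power of the two-sample t test
#'
#' Power for a two-tailed independent-samples t test with equal group
#' sizes, via the noncentral t distribution: noncentrality
#' `effect_d * sqrt(n1 * n2 / (n1 + n2))` with `n_total - 2` degrees of
#' freedom.
#'
#' @param effect_d standardized effect size (Cohen's d), > 0.
#' @param n_total total sample size (even, >= 4); split equally.
#' @param alpha_level two-tailed significance level (default 0.05).
#' @return the power (a single number in (0, 1)).
#' @examples
#' power_two_sample_t(0.8, 24)   # 0.458
#' power_two_sample_t(0.8, 48)   # 0.774
#' @export
power_two_sample_t <- function(effect_d, n_total, alpha_level = 0.05) {
  if (!is.numeric(effect_d) || effect_d <= 0) {
    stop("'effect_d' must be positive", call. = FALSE)
  }
  if (!is.numeric(n_total) || n_total < 4 || n_total %% 2 != 0) {
    stop("'n_total' must be an even total of at least 4", call. = FALSE)
  }
  n1 <- n_total / 2
  df <- n_total - 2
  ncp <- effect_d * sqrt(n1 * n1 / (2 * n1))
  tcrit <- qt(1 - alpha_level / 2, df)
  pt(tcrit, df, ncp = ncp, lower.tail = FALSE) + pt(-tcrit, df, ncp = ncp)
}
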