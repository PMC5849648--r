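#' Polynomial trend regression with effect sizes
#'
#' Least-squares fit of `y` on a degree-1 or degree-2 polynomial in
#' `x`, optionally with extra predictors, reporting adjusted R^2 and,
#' per coefficient, the t statistic, p value and Cohen's d computed as
#' `2 t / sqrt(df)` — the standard conversion for regression
#' coefficients.
#'
#' @param x predictor (e.g. release year).
#' @param y response (e.g. per-movie Whittle estimate).
#' @param degree 1 (linear) or 2 (quadratic).
#' @param extra optional data.frame (or named list) of additional
#'   predictors entered alongside the polynomial.
#' @return object of class `"trend_fit"`: `coefficients`,
#'   `adjusted_R2`, `t_statistics`, `p_values`, `cohens_d`, `df`,
#'   `degree`, and the underlying `lm` fit.
#' @examples
#' f <- fit_trend(1:20, 2 * (1:20) + rnorm(20, 0, 0.1))
#' f$coefficients
#' @export
fit_trend <- function(x, y, degree = 1L, extra = NULL) {
  if (!degree %in% c(1L, 2L)) stop("'degree' must be 1 or 2", call. = FALSE)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < degree + 2L) stop("too few points", call. = FALSE)
  dat <- data.frame(y = y, x1 = x)
  form <- "y ~ x1"
  if (degree == 2L) {
    dat$x2 <- x^2
    form <- "y ~ x1 + x2"
  }
  if (!is.null(extra)) {
    extra <- as.data.frame(extra)
    stopifnot(nrow(extra) == length(y))
    dat <- cbind(dat, extra)
    form <- paste(form, "+", paste(names(extra), collapse = " + "))
  }
  fit <- lm(stats::as.formula(form), data = dat)
  if (fit$rank < length(coef(fit))) {
    stop("rank-deficient design (collinear predictors)", call. = FALSE)
  }
  sm <- summary(fit)
  tt <- sm$coefficients[, "t value"]
  pp <- sm$coefficients[, "Pr(>|t|)"]
  dfres <- fit$df.residual
  structure(list(coefficients = coef(fit),
                 adjusted_R2 = sm$adj.r.squared,
                 t_statistics = tt, p_values = pp,
                 cohens_d = 2 * tt / sqrt(dfres),
                 df = dfres, degree = degree, fit = fit),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Trend fit (degree %d): adjusted R^2 = %.3f, df = %d\n",
              x$degree, x$adjusted_R2, x$df))
  tab <- data.frame(estimate = signif(x$coefficients, 4),
                    t = round(x$t_statistics, 2),
                    p = signif(x$p_values, 3),
                    d = round(x$cohens_d, 2))
  print(tab)
  invisible(x)
}

#' Two-lines test for a U-shaped trend
#'
#' Fits independent linear regressions on the two sides of a
#' breakpoint and declares the relationship U-shaped (or inverted-U)
#' only when both slopes are individually significant with opposite
#' signs.  A significant quadratic term alone is not sufficient
#' evidence of a U shape.
#'
#' @param x,y numeric vectors.
#' @param breakpoint split point: left side `x < breakpoint`, right
#'   side `x >= breakpoint`.
#' @param alpha_level significance level per side (default 0.05).
#' @return list with `left` and `right` ([fit_trend()] objects) and a
#'   `verdict`: `"u_shaped"`, `"inverted_u"` or `"not_u"`.
#' @export
two_lines_test <- function(x, y, breakpoint, alpha_level = 0.05) {
  li <- x < breakpoint
  if (sum(li) < 4L || sum(!li) < 4L) {
    stop("need at least 4 points on each side of the breakpoint",
         call. = FALSE)
  }
  left <- fit_trend(x[li], y[li], degree = 1L)
  right <- fit_trend(x[!li], y[!li], degree = 1L)
  sl <- left$coefficients[["x1"]]; sr <- right$coefficients[["x1"]]
  pl <- left$p_values[["x1"]]; pr <- right$p_values[["x1"]]
  verdict <- "not_u"
  if (pl < alpha_level && pr < alpha_level) {
    if (sl < 0 && sr > 0) verdict <- "u_shaped"
    if (sl > 0 && sr < 0) verdict <- "inverted_u"
  }
  list(left = left, right = right, verdict = verdict)
}

#' Stepwise variance partitioning for two predictors
#'
#' R^2 increments for both entry orders: how much variance `x1`
#' explains alone, how much `x2` adds, and vice versa.  The two orders
#' are consistent (`R2_x1_first + delta_x2 == R2_x2_first + delta_x1`,
#' both equal the full-model R^2).
#'
#' @param y response.
#' @param x1,x2 predictors.
#' @return list: `R2_x1_first`, `delta_x2`, `R2_x2_first`, `delta_x1`,
#'   `R2_full`.
#' @export
stepwise_partition <- function(y, x1, x2) {
  n <- length(y)
  stopifnot(length(x1) == n, length(x2) == n)
  if (n <= 10L) stop("need more than 10 observations", call. = FALSE)
  if (abs(cor(x1, x2)) > 1 - 1e-12) {
    stop("predictors are collinear to machine precision", call. = FALSE)
  }
  r2 <- function(fit) summary(fit)$r.squared
  R1 <- r2(lm(y ~ x1))
  R2 <- r2(lm(y ~ x2))
  Rf <- r2(lm(y ~ x1 + x2))
  list(R2_x1_first = R1, delta_x2 = Rf - R1,
       R2_x2_first = R2, delta_x1 = Rf - R2,
       R2_full = Rf)
}

#' Pearson correlation with t test
#'
#' @param a,b numeric vectors of equal length (>= 4).
#' @return list: `r`, `t`, `p`, `df`.
#' @export
correlate <- function(a, b) {
  n <- length(a)
  if (length(b) != n || n < 4L) {
    stop("'a' and 'b' must have equal length >= 4", call. = FALSE)
  }
  if (sd(a) == 0 || sd(b) == 0) stop("zero variance input", call. = FALSE)
  r <- cor(a, b)
  df <- n - 2L
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, t = t, p = 2 * pt(-abs(t), df), df = df)
}

#' Compare estimator stability by coefficient of variation
#'
#' For each cell of a calibration grid (excluding the intended-alpha-0
#' cells, whose near-zero means make the ratio unstable), computes the
#' coefficient of variation (sd/mean) of the slope and Whittle
#' estimates and runs a paired t test across cells.
#'
#' @param grid an [alpha_length_grid()] result with slope estimates.
#' @return list: `cells` (per-cell CVs), `share_whittle_smaller`,
#'   `t_test` (paired), `n_cells`.
#' @export
cv_compare <- function(grid) {
  stopifnot(inherits(grid, "alpha_length_grid"))
  cells <- grid$cells[grid$cells$intended_alpha > 0, ]
  eps <- 1e-8
  keep <- abs(cells$slope_mean) > eps & abs(cells$whittle_mean) > eps
  if (any(!keep)) {
    warning(sprintf("%d cell(s) with near-zero mean dropped", sum(!keep)),
            call. = FALSE)
    cells <- cells[keep, ]
  }
  if (nrow(cells) < 2L) stop("not enough cells to compare", call. = FALSE)
  cells$cv_slope <- cells$slope_sd / cells$slope_mean
  cells$cv_whittle <- cells$whittle_sd / cells$whittle_mean
  tt <- tryCatch(t.test(cells$cv_slope, cells$cv_whittle, paired = TRUE),
                 error = function(e) NULL)   # identical CVs: no test possible
  list(cells = cells,
       share_whittle_smaller = mean(cells$cv_whittle < cells$cv_slope),
       t_test = tt, n_cells = nrow(cells))
}
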