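test_that("trend fits agree with the normal-equations oracle", {
  set.seed(71)
  x <- rnorm(40, 0, 2)        # centered predictor keeps X'X well conditioned
  z <- rnorm(40)
  y <- 0.3 + 0.4 * x - 0.05 * x^2 + 0.5 * z + rnorm(40, 0, 0.3)
  f <- fit_trend(x, y, degree = 2, extra = data.frame(z = z))
  o <- oracle_ols(cbind(1, x, x^2, z), y)
  expect_equal(unname(f$coefficients), unname(o$beta), tolerance = 1e-8)
  expect_equal(unname(f$t_statistics), unname(o$t), tolerance = 1e-8)
  expect_equal(f$adjusted_R2, o$adj_r2, tolerance = 1e-8)
  expect_equal(unname(f$cohens_d), unname(2 * o$t / sqrt(o$df)),
               tolerance = 1e-10)
})

test_that("trend fitting handles exact, null and quadratic cases", {
  x <- 1:50
  f <- suppressWarnings(fit_trend(x, 2 * x))   # lm warns on a perfect fit
  expect_equal(f$adjusted_R2, 1, tolerance = 1e-12)
  expect_equal(f$coefficients[["x1"]], 2, tolerance = 1e-12)
  set.seed(720)
  f0 <- fit_trend(rnorm(200), rnorm(200))
  expect_lt(abs(f0$adjusted_R2), 0.03)
  expect_lt(abs(f0$t_statistics[["x1"]]), 2)
  # a true quadratic beats a linear-only fit
  set.seed(73)
  yr <- runif(150, 1915, 2015)
  yq <- (yr - 1960)^2 / 1000 + rnorm(150, 0, 0.5)
  f2 <- fit_trend(yr, yq, degree = 2)
  f1 <- fit_trend(yr, yq, degree = 1)
  expect_lt(f2$p_values[["x2"]], 1e-6)
  expect_gt(f2$adjusted_R2, f1$adjusted_R2)
  expect_error(fit_trend(x, 2 * x, extra = data.frame(w = x)), "collinear|rank")
})

test_that("the two-lines test sorts U, monotone and flat shapes", {
  set.seed(74)
  x <- runif(200, 1915, 2015)
  v <- abs(x - 1960) / 20 + rnorm(200, 0, 0.4)
  expect_identical(two_lines_test(x, v, 1960)$verdict, "u_shaped")
  expect_identical(two_lines_test(x, -v, 1960)$verdict, "inverted_u")
  mono <- 0.01 * x + rnorm(200, 0, 0.2)
  expect_identical(two_lines_test(x, mono, 1960)$verdict, "not_u")
  flat <- rnorm(200)
  expect_identical(two_lines_test(x, flat, 1960)$verdict, "not_u")
  expect_error(two_lines_test(x, v, 1916), "4 points")
})

test_that("stepwise partitioning is order-consistent and matches closed forms", {
  set.seed(75)
  n <- 400
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  y <- x1 + x2 + rnorm(n)
  p <- stepwise_partition(y, x1, x2)
  expect_equal(p$R2_x1_first + p$delta_x2, p$R2_x2_first + p$delta_x1,
               tolerance = 1e-9)
  o <- oracle_r2_from_cov(y, x1, x2)
  expect_equal(p$R2_x1_first, o$x1, tolerance = 1e-10)
  expect_equal(p$R2_x2_first, o$x2, tolerance = 1e-10)
  expect_equal(p$R2_full, o$full, tolerance = 1e-10)
  # pure-noise second predictor adds essentially nothing
  p0 <- stepwise_partition(y, x1, rnorm(n))
  expect_lt(p0$delta_x2, 0.02)
  # correlated predictors still satisfy the covariance closed form
  x3 <- 0.7 * x1 + 0.3 * rnorm(n)
  p3 <- stepwise_partition(y, x1, x3)
  o3 <- oracle_r2_from_cov(y, x1, x3)
  expect_equal(p3$R2_full, o3$full, tolerance = 1e-10)
  expect_error(stepwise_partition(y, x1, x1), "collinear")
})

test_that("correlation wrapper matches cor.test and behaves on edge cases", {
  set.seed(76)
  a <- rnorm(100); b <- 0.6 * a + 0.8 * rnorm(100)
  got <- correlate(a, b)
  ref <- cor.test(a, b)
  expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  expect_equal(correlate(a, a)$r, 1)
  means <- mean(replicate(100, {
    x <- rnorm(263); y <- 0.6 * x + 0.8 * rnorm(263); cor(x, y)
  }))
  expect_equal(means, 0.6, tolerance = 0.02)
  expect_error(correlate(a, rep(1, 100)), "zero variance")
})

test_that("cv_compare flags trivial and degenerate grids", {
  cells <- data.frame(intended_alpha = rep(c(0, 0.5, 1), each = 2),
                      length = rep(c(512, 1024), 3), reps = 10,
                      slope_mean = rep(c(0.1, 0.5, 1), each = 2),
                      slope_sd = 0.2,
                      whittle_mean = rep(c(0.05, 0.25, 0.5), each = 2),
                      whittle_sd = 0.1)
  g <- structure(list(cells = cells, reps = 10), class = "alpha_length_grid")
  out <- cv_compare(g)
  expect_equal(out$n_cells, 4)                      # alpha = 0 rows excluded
  expect_equal(out$cells$cv_slope, out$cells$cv_whittle, tolerance = 1e-12)
  g1 <- structure(list(cells = cells[3, , drop = FALSE], reps = 10),
                  class = "alpha_length_grid")
  expect_error(cv_compare(g1), "not enough cells")
})
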