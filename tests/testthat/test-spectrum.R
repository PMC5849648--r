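test_that("window bookkeeping is exact", {
  x <- colored_noise(600, 0.5, seed = 3)
  sp <- windowed_power(x)
  expect_identical(sp$window_lengths, 2L^(1:8))
  expect_identical(sp$n_windows, 600L - 2L^(1:8) + 1L)
  expect_true(all(sp$mean_power > 0))
})

test_that("white noise has a flat windowed spectrum", {
  set.seed(8)
  P <- rowMeans(sapply(1:60, function(i) {
    windowed_power(normalize_series(rnorm(4096)))$mean_power
  }))
  expect_lt(max(P) / min(P), 1.3)
})

test_that("a pure sinusoid concentrates power at its own wavelength", {
  x <- sin(2 * pi * (0:511) / 8)
  sp <- windowed_power(normalize_series(x), min_length = 512)
  p <- sp$mean_power
  L <- sp$window_lengths
  expect_gt(p[L == 8] / p[L == 2], 10)
  expect_gt(p[L == 8], max(p[L != 8]))
})

test_that("short, constant and unnormalized inputs are handled", {
  expect_error(windowed_power(rnorm(500)), "too short")
  expect_error(windowed_power(rep(2, 600)), "degenerate")
  expect_warning(windowed_power(rnorm(600) * 5 + 3), "not normalized")
})

test_that("the hybrid fit recovers an exactly generated spectrum", {
  L <- 2^(1:8)
  sp <- structure(list(window_lengths = L,
                       mean_power = 2 * L^0.7 + 0.5,
                       n_windows = 1024L - L + 1L, n = 1024L),
                  class = "windowed_spectrum")
  fit <- fit_hybrid(sp)
  expect_equal(fit$alpha, 0.7, tolerance = 1e-3)
  expect_equal(fit$colored_scale, 2, tolerance = 1e-2)
  expect_equal(fit$white_level, 0.5, tolerance = 1e-2)
  expect_lt(fit$rmsd_log, 1e-4)
})

test_that("the slope is scale and shift invariant", {
  set.seed(10)
  x <- as.numeric(colored_noise(1024, 0.8, seed = 10))
  f0 <- fractal_fit(x)
  f1 <- fractal_fit(37.5 * x)
  f2 <- fractal_fit(x + 12)
  expect_equal(f1$slope$alpha, f0$slope$alpha, tolerance = 1e-8)
  expect_equal(f2$slope$alpha, f0$slope$alpha, tolerance = 1e-6)
  expect_equal(f1$whittle$d, f0$whittle$d, tolerance = 1e-8)
  expect_equal(f2$whittle$d, f0$whittle$d, tolerance = 1e-6)
})

test_that("fitted alpha on iid input stays near zero", {
  set.seed(12)
  a <- replicate(200, {
    fit_hybrid(windowed_power(normalize_series(rnorm(1024))))$alpha
  })
  expect_lt(mean(a), 0.15)
})

test_that("on white input the white component dominates the fit", {
  set.seed(13)
  ratio <- replicate(50, {
    f <- fit_hybrid(windowed_power(colored_noise(1024, 0)))
    f$colored_scale * 256^f$alpha / f$white_level
  })
  expect_true(all(ratio < 10))
})

test_that("pink noise yields a slope near one", {
  a <- sapply(1:100, function(s) {
    fit_hybrid(windowed_power(colored_noise(1024, 1, seed = 5000 + s)))$alpha
  })
  expect_lt(abs(mean(a) - 1), 0.15)
})

test_that("fit quality improves with series length", {
  rmsd_at <- function(n, seeds) {
    mean(sapply(seeds, function(s) {
      fit_hybrid(windowed_power(colored_noise(n, 0.5, seed = s)))$rmsd_log
    }))
  }
  expect_lt(rmsd_at(2048, 301:330), rmsd_at(512, 301:330))
})

test_that("short series are excluded from the slope, not crashed", {
  x <- colored_noise(500, 1, seed = 6)
  expect_message(f <- fractal_fit(x), "excluded")
  expect_null(f$slope)
  expect_true(f$slope_excluded)
  expect_s3_class(f$whittle, "whittle_fit")
})
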