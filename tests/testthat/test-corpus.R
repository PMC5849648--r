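test_that("rank remapping preserves the marginal exactly and the rank order", {
  set.seed(61)
  col <- colored_noise(500, 1, seed = 61)
  marg <- rlnorm(500, 1, 0.7)
  out <- impose_spectrum_with_marginals(col, marg)
  expect_equal(sort(as.numeric(out)), sort(marg), tolerance = 1e-12)
  expect_identical(rank(as.numeric(out), ties.method = "first"),
                   rank(as.numeric(col), ties.method = "first"))
  # a monotone transform of the marginal leaves the rank order unchanged
  out2 <- impose_spectrum_with_marginals(col, log(marg))
  expect_identical(order(as.numeric(out2)), order(as.numeric(out)))
  expect_error(impose_spectrum_with_marginals(col, marg[-1]), "equal length")
})

test_that("rank remapping onto skewed marginals barely distorts measured memory", {
  set.seed(62)
  dd <- sapply(1:30, function(i) {
    col <- colored_noise(1024, 1, seed = 300 + i)
    out <- impose_spectrum_with_marginals(col, rlnorm(1024, log(5), 0.8))
    local_whittle(out)$d - local_whittle(col)$d
  })
  expect_lt(mean(abs(dd)), 0.1)
})

test_that("a generated corpus respects its structural invariants", {
  co <- generate_corpus(corpus_spec(25, master_seed = 101))
  ns <- vapply(co, `[[`, numeric(1), "n_shots")
  expect_true(all(ns >= 188 & ns <= 3235))
  yrs <- vapply(co, `[[`, numeric(1), "year")
  expect_true(all(yrs >= 1915 & yrs <= 2015))
  for (m in co) {
    sc <- as.numeric(m$series$shot_scale)
    expect_true(all(sc == round(sc) & sc >= 1 & sc <= 7))
    expect_true(all(as.numeric(m$series$shot_duration) > 0))
    expect_true(all(m$true_d >= 0 & m$true_d <= 1.1))
    lum <- as.numeric(m$series$luminance)
    expect_true(all(lum >= 0 & lum <= 255))
  }
  # deterministic under the master seed
  co2 <- generate_corpus(corpus_spec(25, master_seed = 101))
  expect_equal(as.numeric(co[[7]]$series$motion),
               as.numeric(co2[[7]]$series$motion), tolerance = 1e-12)
})

test_that("measured memory recovers the injected per-movie targets", {
  co <- generate_corpus(corpus_spec(100, master_seed = 202))
  truth <- vapply(co, function(m) m$true_d[["shot_duration"]], numeric(1))
  meas <- vapply(co, function(m) {
    local_whittle(m$series$shot_duration)$d
  }, numeric(1))
  f <- fit_trend(truth, meas)
  expect_gt(f$coefficients[["x1"]], 0.8)
  expect_gt(correlate(truth, meas)$r, 0.8)
})

test_that("a corpus round-trips through its CSV representation", {
  co <- generate_corpus(corpus_spec(3, master_seed = 303))
  dir <- tempfile("corpus")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  write_corpus(co, dir)
  co2 <- read_corpus(dir)
  expect_length(co2, 3)
  expect_identical(co2[[2]]$movie_id, co[[2]]$movie_id)
  expect_identical(co2[[2]]$year, co[[2]]$year)
  expect_equal(co2[[2]]$true_d, co[[2]]$true_d, tolerance = 1e-12)
  expect_equal(as.numeric(co2[[2]]$series$shot_duration),
               as.numeric(co[[2]]$series$shot_duration), tolerance = 1e-10)
  expect_identical(attr(co2[[2]]$series$motion, "dimension"), "motion")
})

test_that("injected year trends are recovered in the right directions", {
  co <- generate_corpus(corpus_spec(200, master_seed = 404))
  tb <- corpus_table(co, estimator = "whittle")
  post <- tb[tb$year >= 1960, ]
  tr <- function(dm) {
    d <- post[post$dimension == dm, ]
    fit_trend(d$year, d$whittle_d)
  }
  # rising for the attention-linked dimensions
  expect_gt(tr("shot_duration")$t_statistics[["x1"]], 2)
  expect_gt(tr("scene_duration")$t_statistics[["x1"]], 2)
  expect_gt(tr("motion")$t_statistics[["x1"]], 2)
  # falling for sound (declines from near-brown toward the fractal value)
  expect_lt(tr("sound")$t_statistics[["x1"]], -2)
  # flat for style dimensions
  expect_gt(tr("luminance")$p_values[["x1"]], 0.05)
  expect_gt(tr("clutter")$p_values[["x1"]], 0.05)
  expect_gt(tr("shot_scale")$p_values[["x1"]], 0.05)
  # the length confound is present by construction: shot counts and
  # measured memory rise together
  sd_rows <- tb[tb$dimension == "shot_duration", ]
  expect_gt(correlate(sd_rows$n, sd_rows$whittle_d)$r, 0)
})
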