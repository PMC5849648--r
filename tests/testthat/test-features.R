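make_frames <- function(n, dim = 16, fun) lapply(seq_len(n), fun)

test_that("motion is 1 for stillness and near 0 for independent frames", {
  set.seed(51)
  base <- matrix(runif(16 * 16, 0, 255), 16, 16)
  still <- frame_stack(make_frames(6, fun = function(i) base))
  expect_equal(as.numeric(motion_per_shot(still)), 1, tolerance = 1e-12)
  indep <- frame_stack(make_frames(52, fun = function(i) {
    matrix(runif(32 * 32, 0, 255), 32, 32)
  }))
  expect_lt(abs(as.numeric(motion_per_shot(indep))), 0.05)
})

test_that("motion pairs are counted within shot boundaries only", {
  set.seed(52)
  st <- frame_stack(make_frames(20, fun = function(i) {
    matrix(rnorm(64), 8, 8)
  }), shot_boundaries = c(1L, 11L))
  m <- motion_per_shot(st)
  expect_length(as.numeric(m), 2)
  expect_identical(attr(m, "n_pairs"), c(8L, 8L))  # (t, t+2) pairs in 10 frames
})

test_that("motion is invariant to affine intensity rescaling", {
  set.seed(53)
  fr <- make_frames(8, fun = function(i) matrix(rnorm(256, 100, 20), 16, 16))
  m1 <- as.numeric(motion_per_shot(frame_stack(fr)))
  fr2 <- lapply(fr, function(f) 0.5 * f + 30)
  m2 <- as.numeric(motion_per_shot(frame_stack(fr2)))
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("a shot too short for motion gets NA, not an error", {
  st <- frame_stack(make_frames(2, fun = function(i) matrix(i + 0:3, 2, 2)))
  expect_true(is.na(as.numeric(motion_per_shot(st))))
})

test_that("luminance is the mean of per-frame medians", {
  st <- frame_stack(list(matrix(100, 4, 4), matrix(100, 4, 4)))
  expect_equal(as.numeric(luminance_per_shot(st)), 100)
  m40 <- matrix(40, 5, 5); m40[1, 1] <- 40     # median 40
  m60 <- matrix(60, 5, 5)
  st2 <- frame_stack(list(m40, m60))
  expect_equal(as.numeric(luminance_per_shot(st2)), 50)
  # half-black/half-white: R's even-n median averages the middle pair
  checker <- matrix(c(0, 255), 16, 16)
  st3 <- frame_stack(list(checker))
  expect_equal(as.numeric(luminance_per_shot(st3)), 127.5)
})

test_that("clutter is 0 on blank frames and samples every tenth frame", {
  blank <- matrix(128, 32, 32)
  st <- frame_stack(make_frames(25, fun = function(i) blank))
  cl <- clutter_per_shot(st)
  expect_equal(as.numeric(cl), 0)
  expect_identical(attr(cl, "frames_sampled"), 3L)  # frames 1, 11, 21
})

test_that("clutter on a step edge matches the brute-force spatial oracle", {
  img <- matrix(0, 48, 48)
  img[, 25:48] <- 255
  st <- frame_stack(list(img))
  got <- as.numeric(clutter_per_shot(st, sigma = 2, threshold_frac = 0.05))
  oracle <- mean(oracle_log_edge_map(img, 2, 0.05))
  expect_equal(got, oracle, tolerance = 1e-8)
  expect_gt(got, 0)
  expect_lt(got, 0.2)
})

test_that("sound bins have the right count and RMS values", {
  # constant-amplitude sinusoid: every bin equal within 1%
  rate <- 2400
  t <- seq_len(30 * rate) / rate
  au <- audio_track(sin(2 * pi * 440 * t), rate = rate)
  b <- as.numeric(sound_amplitude_bins(au))
  expect_length(b, 7)                      # floor(30 / 4.1667)
  expect_lt(max(b) / min(b) - 1, 0.01)
  expect_equal(b[1], 1 / sqrt(2), tolerance = 1e-3)
  # silence
  sil <- audio_track(rep(0, 10 * rate), rate = rate)
  expect_true(all(as.numeric(sound_amplitude_bins(sil)) == 0))
  # 10-minute track: floor(600 / 4.1667) = 144 bins
  au2 <- synth_audio(600, rate = 2000, seed = 1)
  expect_length(as.numeric(sound_amplitude_bins(au2)), 144)
  # stereo channels are averaged
  stereo <- audio_track(cbind(rep(1, rate * 5), rep(-1, rate * 5)),
                        rate = rate)
  expect_equal(as.numeric(sound_amplitude_bins(stereo)), 0)
})

test_that("the synthetic stack hits its motion and luminance targets", {
  st <- synth_frame_stack(5, 14, dim = 64, target_motion = 0.8,
                          luminance = c(60, 100, 140, 180, 220), seed = 77)
  m <- as.numeric(motion_per_shot(st))
  expect_lt(max(abs(m - 0.8)), 0.05)
  lum <- as.numeric(luminance_per_shot(st))
  expect_lt(max(abs(lum - c(60, 100, 140, 180, 220))), 6)
})

test_that("extracted features run end to end through the estimator", {
  st <- synth_frame_stack(40, 5, dim = 16, target_motion = 0.6, seed = 78)
  m <- motion_per_shot(st)
  f <- local_whittle(m)
  expect_s3_class(f, "whittle_fit")
  expect_true(is.finite(f$d))
})

test_that("frame stacks validate their boundaries", {
  fr <- make_frames(5, fun = function(i) matrix(0, 2, 2))
  expect_error(frame_stack(fr, c(2L, 4L)), "start at 1")
  expect_error(frame_stack(fr, c(1L, 9L)), "within the stack")
  expect_error(frame_stack(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               "equal size")
})
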