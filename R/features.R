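#' Construct a frame stack
#'
#' A frame stack is a movie fragment as a list of grayscale frames
#' (numeric matrices with values 0-255, all the same size) plus the
#' frame indices at which shots begin.  Real pipelines downsample
#' frames to 256 x 256; synthetic stacks for testing may be smaller.
#'
#' @param frames list of numeric matrices, identical dimensions,
#'   values in \[0, 255\].
#' @param shot_boundaries strictly increasing 1-based frame indices of
#'   shot starts; the first must be 1.
#' @param fps frames per second (default 24).
#' @return object of class `"frame_stack"`.
#' @export
frame_stack <- function(frames, shot_boundaries = 1L, fps = 24) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop("'frames' must be a non-empty list of matrices", call. = FALSE)
  }
  dm <- dim(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), dm),
               logical(1))
  if (!all(ok)) stop("all frames must be matrices of equal size", call. = FALSE)
  shot_boundaries <- as.integer(shot_boundaries)
  if (shot_boundaries[1] != 1L || is.unsorted(shot_boundaries, strictly = TRUE) ||
      any(shot_boundaries > length(frames))) {
    stop("'shot_boundaries' must start at 1, increase strictly, and lie within the stack",
         call. = FALSE)
  }
  structure(list(frames = frames, shot_boundaries = shot_boundaries,
                 fps = fps),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frames (%dx%d), %d shot(s), %g fps\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              length(x$shot_boundaries), x$fps))
  invisible(x)
}

# per-shot frame index ranges
shot_ranges <- function(stack) {
  b <- stack$shot_boundaries
  e <- c(b[-1] - 1L, length(stack$frames))
  Map(seq.int, b, e)
}

#' Per-shot motion from inter-frame correlation
#'
#' Motion within a shot is measured as the mean Pearson correlation of
#' pixel values between frames two apart (t and t + 2, skipping one
#' frame to dodge digitization and frame-doubling artifacts), over all
#' pairs lying wholly within the shot.  1 is perfect stillness; low
#' values mean much motion.  Shots with fewer than 3 frames have no
#' valid pair and receive NA.
#'
#' @param stack a [frame_stack()].
#' @return an [event_series()] (dimension `"motion"`) with one value
#'   per shot and attribute `n_pairs` giving pairs used per shot.
#' @export
motion_per_shot <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  rngs <- shot_ranges(stack)
  vals <- numeric(length(rngs))
  npair <- integer(length(rngs))
  for (i in seq_along(rngs)) {
    idx <- rngs[[i]]
    if (length(idx) < 3L) {
      vals[i] <- NA_real_
      next
    }
    ts <- idx[seq_len(length(idx) - 2L)]
    r <- vapply(ts, function(t) {
      a <- as.vector(stack$frames[[t]])
      b <- as.vector(stack$frames[[t + 2L]])
      if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
      cor(a, b)
    }, numeric(1))
    vals[i] <- mean(r, na.rm = TRUE)
    npair[i] <- length(ts)
  }
  out <- structure(vals, movie_id = NA_character_, year = NA_integer_,
                   dimension = "motion", class = "event_series")
  attr(out, "n_pairs") <- npair
  out
}

#' Per-shot luminance
#'
#' The median pixel value of each frame, averaged over the frames of
#' each shot.
#'
#' @param stack a [frame_stack()].
#' @return an [event_series()] (dimension `"luminance"`), one value per
#'   shot, in \[0, 255\].
#' @export
luminance_per_shot <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  vals <- vapply(shot_ranges(stack), function(idx) {
    mean(vapply(stack$frames[idx], function(f) median(as.vector(f)),
                numeric(1)))
  }, numeric(1))
  structure(vals, movie_id = NA_character_, year = NA_integer_,
            dimension = "luminance", class = "event_series")
}

# Laplacian-of-Gaussian kernel, side 2*ceil(3 sigma)+1
log_kernel <- function(sigma) {
  h <- ceiling(3 * sigma)
  g <- seq(-h, h)
  xx <- outer(g^2, rep(1, length(g)))
  r2 <- xx + t(xx)
  k <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k - mean(k)                       # zero response on flat regions
}

# binary edge map: zero crossing of the LoG response with magnitude gate
log_edges <- function(frame, sigma, threshold_frac) {
  resp <- EBImage::filter2(frame, log_kernel(sigma), boundary = "replicate")
  thr <- threshold_frac * max(abs(resp))
  nr <- nrow(resp); nc <- ncol(resp)
  sgn <- sign(resp)
  sgn[abs(resp) < 1e-9 * max(abs(resp))] <- 0   # flat regions are not crossings
  zc <- matrix(FALSE, nr, nc)
  zc[-nr, ] <- zc[-nr, ] | (sgn[-nr, ] * sgn[-1, ] < 0)
  zc[, -nc] <- zc[, -nc] | (sgn[, -nc] * sgn[, -1] < 0)
  zc & (abs(resp) > thr)
}

#' Per-shot clutter from Laplacian-of-Gaussian edge density
#'
#' Every `stride`-th frame within each shot (starting at the shot's
#' first frame) is passed through a Laplacian of Gaussian filter; a
#' pixel is an edge pixel when the response changes sign towards its
#' right or lower neighbour and its magnitude exceeds
#' `threshold_frac * max |response|`.  Clutter for the frame is the
#' proportion of edge pixels, and the shot value is the mean over its
#' sampled frames.  More edges are read as more objects and textures.
#'
#' @param stack a [frame_stack()].
#' @param sigma Gaussian scale in pixels (default 2).
#' @param threshold_frac magnitude gate as a fraction of the maximum
#'   absolute response (default 0.05).
#' @param stride frame sampling stride within a shot (default 10).
#' @return an [event_series()] (dimension `"clutter"`), values in \[0, 1\],
#'   with attribute `frames_sampled` per shot.
#' @export
clutter_per_shot <- function(stack, sigma = 2, threshold_frac = 0.05,
                             stride = 10L) {
  stopifnot(inherits(stack, "frame_stack"))
  rngs <- shot_ranges(stack)
  sampled <- integer(length(rngs))
  vals <- vapply(seq_along(rngs), function(i) {
    idx <- rngs[[i]]
    pick <- idx[seq(1L, length(idx), by = stride)]
    sampled[i] <<- length(pick)
    mean(vapply(stack$frames[pick], function(f) {
      if (max(f) == min(f)) return(0)           # blank frame: no edges
      mean(log_edges(f, sigma, threshold_frac))
    }, numeric(1)))
  }, numeric(1))
  out <- structure(vals, movie_id = NA_character_, year = NA_integer_,
                   dimension = "clutter", class = "event_series")
  attr(out, "frames_sampled") <- sampled
  out
}

#' Construct an audio track
#'
#' @param samples numeric vector, or a two-column matrix of stereo
#'   samples (channels are averaged before analysis).
#' @param rate samples per second (default 44000).
#' @return object of class `"audio_track"`.
#' @export
audio_track <- function(samples, rate = 44000) {
  if (rate <= 0) stop("'rate' must be positive", call. = FALSE)
  if (is.matrix(samples)) samples <- rowMeans(samples)
  structure(list(samples = as.numeric(samples), rate = rate),
            class = "audio_track")
}

#' Binned sound amplitude
#'
#' Divides the track into bins of `bin_frames` video frames
#' (100 frames at 24 fps is 4.17 s) and returns the RMS amplitude of
#' each bin.  A trailing partial bin is dropped.  Sound flows across
#' cuts, so binning ignores shot structure.
#'
#' @param audio an [audio_track()].
#' @param fps video frame rate the bins are defined against (default 24).
#' @param bin_frames bin width in video frames (default 100).
#' @return an [event_series()] (dimension `"sound"`), one RMS value per
#'   bin.
#' @export
sound_amplitude_bins <- function(audio, fps = 24, bin_frames = 100L) {
  stopifnot(inherits(audio, "audio_track"))
  spb <- round(audio$rate * bin_frames / fps)   # samples per bin
  nb <- length(audio$samples) %/% spb
  if (nb < 1L) stop("track shorter than one bin", call. = FALSE)
  s <- audio$samples[seq_len(nb * spb)]
  m <- matrix(s, nrow = spb)
  vals <- sqrt(colMeans(m^2))
  structure(vals, movie_id = NA_character_, year = NA_integer_,
            dimension = "sound", class = "event_series")
}

#' Synthesise a frame stack with controlled motion and luminance
#'
#' Builds a grayscale frame stack for testing the feature operators.
#' Within each shot, frames share a common random field with weight
#' `sqrt(target_motion)` plus independent noise, so the expected
#' inter-frame correlation equals `target_motion`.  Optional per-shot
#' luminance pedestals shift the frame medians.
#'
#' @param n_shots number of shots.
#' @param frames_per_shot frames per shot (single value or vector).
#' @param dim frame side length in pixels (default 64).
#' @param target_motion expected inter-frame pixel correlation in
#'   \[0, 1) (default 0.8).
#' @param luminance optional per-shot pedestal values (0-255); default
#'   128 everywhere.
#' @param contrast pixel standard deviation around the pedestal
#'   (default 25).
#' @param seed optional integer seed.
#' @return a [frame_stack()].
#' @export
synth_frame_stack <- function(n_shots, frames_per_shot, dim = 64L,
                              target_motion = 0.8, luminance = NULL,
                              contrast = 25, seed = NULL) {
  if (target_motion < 0 || target_motion >= 1) {
    stop("'target_motion' must be in [0, 1)", call. = FALSE)
  }
  fps_vec <- rep_len(frames_per_shot, n_shots)
  if (is.null(luminance)) luminance <- rep(128, n_shots)
  luminance <- rep_len(luminance, n_shots)
  with_seed(seed, {
    frames <- list()
    bounds <- integer(n_shots)
    pos <- 1L
    for (s in seq_len(n_shots)) {
      bounds[s] <- pos
      shared <- matrix(rnorm(dim * dim), dim, dim)
      for (f in seq_len(fps_vec[s])) {
        z <- sqrt(target_motion) * shared +
          sqrt(1 - target_motion) * matrix(rnorm(dim * dim), dim, dim)
        fr <- luminance[s] + contrast * z
        frames[[pos]] <- pmin(pmax(fr, 0), 255)
        pos <- pos + 1L
      }
    }
    frame_stack(frames, bounds)
  })
}

#' Synthesise an amplitude-modulated noise audio track
#'
#' Gaussian noise multiplied by a deterministic envelope, for testing
#' the sound binning.  The envelope is given per second and linearly
#' interpolated to sample resolution; zero segments give silent bins.
#'
#' @param duration_s track duration in seconds.
#' @param rate samples per second (default 44000).
#' @param envelope numeric vector of nonnegative amplitudes, one per
#'   second (recycled), or a single constant.
#' @param seed optional integer seed.
#' @return an [audio_track()].
#' @export
synth_audio <- function(duration_s, rate = 44000, envelope = 1, seed = NULL) {
  n <- round(duration_s * rate)
  env_sec <- rep_len(envelope, ceiling(duration_s))
  env <- rep(env_sec, each = rate)[seq_len(n)]
  with_seed(seed, audio_track(rnorm(n) * env, rate = rate))
}
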