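#' Impose a spectral structure on a target marginal distribution
#'
#' Rank remapping: the output takes exactly the values of
#' `marginal_sample` (sorted), arranged in the rank order of the
#' colored series.  The marginal distribution is therefore preserved
#' exactly, while the long-range dependence of the colored series is
#' carried over through the ranks (a monotone transform, which the
#' semiparametric estimators tolerate with little distortion).
#'
#' @param colored numeric vector or [event_series()] supplying the rank
#'   order (typically [colored_noise()]).
#' @param marginal_sample numeric vector of the same length supplying
#'   the values.
#' @return numeric vector (or event series, metadata from `colored`).
#' @export
impose_spectrum_with_marginals <- function(colored, marginal_sample) {
  v <- as.numeric(colored)
  if (length(v) != length(marginal_sample)) {
    stop("'colored' and 'marginal_sample' must have equal length",
         call. = FALSE)
  }
  out <- sort(as.numeric(marginal_sample))[rank(v, ties.method = "first")]
  if (inherits(colored, "event_series")) as_series_like(out, colored) else out
}

# year -> mean shot duration (s): about 10 s/shot in 1950 falling to
# about 4 s/shot in 2010, flat outside
mean_shot_duration <- function(year) {
  y <- pmin(pmax(year, 1950), 2010)
  10 - 6 * (y - 1950) / 60
}

# year -> mean scene duration (s): about 90 s in 1940 to 50 s in 2010
mean_scene_duration <- function(year) {
  y <- pmin(pmax(year, 1940), 2010)
  90 - 40 * (y - 1940) / 70
}

# default year -> target memory parameter per dimension: rising after
# 1960 for the attention-relevant dimensions, flat for the others;
# sound falls from near-brown toward the fractal value
default_d_trends <- list(
  shot_duration  = function(y) ifelse(y < 1960, 0.15, 0.12 + 0.23 * (y - 1960) / 55),
  scene_duration = function(y) ifelse(y < 1960, 0.10, 0.10 + 0.30 * (y - 1960) / 55),
  motion         = function(y) ifelse(y < 1960, 0.15, 0.15 + 0.25 * (y - 1960) / 55),
  sound          = function(y) 0.75 - 0.30 * (pmin(pmax(y, 1935), 2015) - 1935) / 80,
  luminance      = function(y) rep(0.56, length(y)),
  clutter        = function(y) rep(0.34, length(y)),
  shot_scale     = function(y) rep(0.22, length(y))
)

#' Specify a synthetic movie corpus
#'
#' Collects the generation parameters for [generate_corpus()]: number
#' of movies, release-year range, the per-dimension year-to-memory
#' trends, and the master seed.  Defaults emulate a century-long
#' popular-film sample: 188-3235 shots per film (more in later years as
#' shots shorten), lognormal right-skewed durations, bounded motion and
#' clutter, scene-pedestal luminance, a 7-level quantized shot scale,
#' and memory parameters that rise after 1960 for shot durations,
#' scene durations, motion and (falling from above) sound, but stay
#' flat for luminance, clutter and shot scale.
#'
#' @param n_movies number of movies.
#' @param year_range inclusive release-year range.
#' @param d_trends named list of functions year -> target d, by
#'   dimension; defaults described above.  Values are jittered per
#'   movie (sd `d_jitter`) and clipped to \[0, 1.1\].
#' @param d_jitter per-movie sd of the target d (default 0.08).
#' @param shot_bounds admissible shot counts (default c(188, 3235)).
#' @param dimensions which dimensions to generate.
#' @param master_seed integer seed; the whole corpus is deterministic
#'   given it.
#' @return object of class `"corpus_spec"`.
#' @export
corpus_spec <- function(n_movies, year_range = c(1915, 2015),
                        d_trends = default_d_trends, d_jitter = 0.08,
                        shot_bounds = c(188, 3235),
                        dimensions = names(default_d_trends),
                        master_seed = 1L) {
  stopifnot(n_movies >= 1, length(year_range) == 2,
            all(dimensions %in% names(d_trends)))
  structure(list(n_movies = as.integer(n_movies),
                 year_range = as.integer(year_range),
                 d_trends = d_trends, d_jitter = d_jitter,
                 shot_bounds = shot_bounds, dimensions = dimensions,
                 master_seed = as.integer(master_seed)),
            class = "corpus_spec")
}

# moderately face-heavy shot-scale level frequencies (1 = extreme long
# shot ... 7 = extreme closeup)
shot_scale_probs <- c(0.06, 0.14, 0.18, 0.22, 0.20, 0.14, 0.06)

#' Generate a synthetic movie corpus
#'
#' For each movie: draw a release year, derive expected shot and scene
#' counts from the era's mean shot and scene durations (a nominal
#' 110-minute feature), jitter and clip them, then build each requested
#' dimension by synthesising colored noise at `alpha = 2.32 * d_target`
#' and rank-remapping it onto a realistic marginal sample
#' ([impose_spectrum_with_marginals()]).  Marginal families: lognormal
#' durations (shots and scenes), Beta-distributed motion (high values =
#' stillness) and clutter, Gaussian per-scene pedestals for luminance,
#' lognormal sound-bin amplitudes, and a 7-level quantile cut of the
#' colored latent for shot scale.
#'
#' @param spec a [corpus_spec()].
#' @return object of class `"movie_corpus"`: a list of movie records,
#'   each with `movie_id`, `year`, `n_shots`, `true_d` (named per
#'   dimension) and `series` (named list of [event_series()]).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  seeds <- spawn_seeds(spec$master_seed, spec$n_movies)
  movies <- vector("list", spec$n_movies)
  for (i in seq_len(spec$n_movies)) {
    movies[[i]] <- with_seed(seeds[i], generate_movie(spec, i))
  }
  structure(movies, class = "movie_corpus")
}

generate_movie <- function(spec, i) {
  year <- sample(seq(spec$year_range[1], spec$year_range[2]), 1L)
  n_shots <- round(110 * 60 / mean_shot_duration(year) * exp(rnorm(1, 0, 0.25)))
  n_shots <- min(max(n_shots, spec$shot_bounds[1]), spec$shot_bounds[2])
  n_scenes <- round(110 * 60 / mean_scene_duration(year) * exp(rnorm(1, 0, 0.2)))
  n_scenes <- min(max(n_scenes, 35), 215)
  n_bins <- round(110 * 60 / (100 / 24) * exp(rnorm(1, 0, 0.1)))

  dims <- spec$dimensions
  true_d <- vapply(dims, function(dm) {
    d <- spec$d_trends[[dm]](year) + rnorm(1, 0, spec$d_jitter)
    min(max(d, 0), 1.1)
  }, numeric(1))

  lens <- vapply(dims, function(dm) {
    switch(dm,
           scene_duration = n_scenes,
           sound = n_bins,
           n_shots)
  }, numeric(1))

  series <- vector("list", length(dims))
  names(series) <- dims
  for (k in seq_along(dims)) {
    dm <- dims[k]
    n <- as.integer(lens[k])
    latent <- colored_noise(n, min(3, 2.32 * true_d[k]))
    marg <- switch(dm,
      shot_duration  = rlnorm(n, log(mean_shot_duration(year)) - 0.32, 0.8),
      scene_duration = rlnorm(n, log(mean_scene_duration(year)) - 0.18, 0.6),
      motion         = rbeta(n, 8, 2),
      sound          = rlnorm(n, 0, 0.5),
      clutter        = 0.3 * rbeta(n, 2, 10),
      luminance      = luminance_pedestal_sample(n),
      shot_scale     = NULL)
    vals <- if (dm == "shot_scale") {
      qs <- quantile(latent, cumsum(shot_scale_probs)[-7], names = FALSE)
      as.numeric(findInterval(as.numeric(latent), qs) + 1L)
    } else {
      impose_spectrum_with_marginals(latent, marg)
    }
    series[[k]] <- event_series(as.numeric(vals),
                                movie_id = sprintf("m%04d", i),
                                year = year, dimension = dm)
  }
  list(movie_id = sprintf("m%04d", i), year = year, n_shots = n_shots,
       true_d = true_d, series = series)
}

# per-scene Gaussian pedestals with small per-shot wiggle (scenes
# average ~11 shots); luminance is a property of the scene more than of
# the shots inside it
luminance_pedestal_sample <- function(n_shots) {
  vals <- numeric(0)
  while (length(vals) < n_shots) {
    len <- 1L + stats::rpois(1, 10)
    ped <- rnorm(1, 120, 35)
    vals <- c(vals, ped + rnorm(len, 0, 6))
  }
  pmin(pmax(vals[seq_len(n_shots)], 5), 250)
}

#' @export
print.movie_corpus <- function(x, ...) {
  yrs <- vapply(x, `[[`, numeric(1), "year")
  ns <- vapply(x, `[[`, numeric(1), "n_shots")
  cat(sprintf("<movie_corpus> %d movies, years %d-%d, shots %d-%d\n",
              length(x), min(yrs), max(yrs), min(ns), max(ns)))
  invisible(x)
}

#' Write a corpus to a directory of CSV files
#'
#' One long-format CSV per movie (`movie_id, year, dimension, index,
#' value`) plus `manifest.csv` with `movie_id`, `year`, `n_shots` and
#' the per-dimension target memory parameters (`d_<dimension>`).
#'
#' @param corpus a [generate_corpus()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "movie_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- do.call(rbind, lapply(corpus, function(m) {
    row <- data.frame(movie_id = m$movie_id, year = m$year,
                      n_shots = m$n_shots)
    for (dm in names(m$true_d)) row[[paste0("d_", dm)]] <- m$true_d[[dm]]
    row
  }))
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  for (m in corpus) {
    rows <- do.call(rbind, lapply(names(m$series), function(dm) {
      v <- as.numeric(m$series[[dm]])
      data.frame(movie_id = m$movie_id, year = m$year, dimension = dm,
                 index = seq_along(v), value = v)
    }))
    write.csv(rows, file.path(dir, paste0(m$movie_id, ".csv")),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Read a corpus written by [write_corpus()]
#'
#' @param dir directory containing `manifest.csv` and per-movie CSVs.
#' @return a `"movie_corpus"`.
#' @export
read_corpus <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"))
  dcols <- grep("^d_", names(man), value = TRUE)
  movies <- lapply(seq_len(nrow(man)), function(i) {
    id <- man$movie_id[i]
    rows <- read.csv(file.path(dir, paste0(id, ".csv")))
    series <- lapply(split(rows, rows$dimension), function(df) {
      df <- df[order(df$index), ]
      event_series(df$value, movie_id = id, year = man$year[i],
                   dimension = df$dimension[1])
    })
    true_d <- as.numeric(man[i, dcols])
    names(true_d) <- sub("^d_", "", dcols)
    list(movie_id = id, year = man$year[i], n_shots = man$n_shots[i],
         true_d = true_d, series = series)
  })
  structure(movies, class = "movie_corpus")
}

#' Run the estimator pipeline over a corpus
#'
#' Applies [fractal_fit()] to every series of every movie and collects
#' a flat results table.  Slopes are reported only for series meeting
#' the `min_shots` eligibility rule; the Whittle estimate is computed
#' for every series of at least `min_whittle` values.
#'
#' @param corpus a `"movie_corpus"`.
#' @param estimator `"whittle"` (default, much faster for trend work)
#'   or `"both"`.
#' @param min_shots slope eligibility threshold.
#' @param bandwidth_exponent Whittle bandwidth rule.
#' @param min_whittle shortest series for the Whittle step; default 16
#'   admits short scene vectors (warnings suppressed, use
#'   [whittle_sd_calibration()] for their standard errors).
#' @return data.frame: `movie_id`, `year`, `dimension`, `n`, `true_d`,
#'   `whittle_d`, `m`, `alpha`, `white_level`, `rmsd_log`.
#' @export
corpus_table <- function(corpus, estimator = c("whittle", "both"),
                         min_shots = 512L, bandwidth_exponent = 0.65,
                         min_whittle = 16L) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(corpus, "movie_corpus"))
  rows <- list()
  for (m in corpus) {
    for (dm in names(m$series)) {
      x <- m$series[[dm]]
      wh <- tryCatch(
        suppressWarnings(local_whittle(x, bandwidth_exponent,
                                       min_length = min_whittle)),
        error = function(e) NULL)
      alpha <- white <- rmsd <- NA_real_
      if (estimator == "both" && length(x) >= min_shots) {
        hf <- tryCatch(fit_hybrid(windowed_power(normalize_series(x))),
                       error = function(e) NULL)
        if (!is.null(hf)) {
          alpha <- hf$alpha; white <- hf$white_level; rmsd <- hf$rmsd_log
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        movie_id = m$movie_id, year = m$year, dimension = dm,
        n = length(x),
        true_d = if (dm %in% names(m$true_d)) m$true_d[[dm]] else NA_real_,
        whittle_d = if (is.null(wh)) NA_real_ else wh$d,
        m = if (is.null(wh)) NA_integer_ else wh$m,
        alpha = alpha, white_level = white, rmsd_log = rmsd)
    }
  }
  do.call(rbind, rows)
}
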