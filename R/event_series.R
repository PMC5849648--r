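#' Construct a film event series
#'
#' An event series is one dimension of one movie as an ordered numeric
#' vector: shot durations, scene durations, per-shot motion, luminance,
#' clutter, shot scale, or binned sound amplitude.  The object is a plain
#' numeric vector carrying movie metadata as attributes, so every
#' function in the package also accepts an ordinary numeric vector.
#'
#' @param values numeric vector of finite values, length at least 2.
#' @param movie_id character identifier.
#' @param year integer release year.
#' @param dimension one of `"shot_duration"`, `"scene_duration"`,
#'   `"motion"`, `"sound"`, `"luminance"`, `"clutter"`, `"shot_scale"`,
#'   `"synthetic"`.
#' @return an object of class `"event_series"`.
#' @examples
#' x <- event_series(rlnorm(600, log(5), 0.8), "m001", 1998, "shot_duration")
#' print(x)
#' @export
event_series <- function(values, movie_id = NA_character_, year = NA_integer_,
                         dimension = c("synthetic", "shot_duration",
                                       "scene_duration", "motion", "sound",
                                       "luminance", "clutter", "shot_scale")) {
  dimension <- match.arg(dimension)
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("an event series needs at least 2 values", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("event series values must be finite", call. = FALSE)
  }
  structure(values,
            movie_id = as.character(movie_id),
            year = as.integer(year),
            dimension = dimension,
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %s | %s | year %s | n = %d\n",
              attr(x, "movie_id"), attr(x, "dimension"),
              attr(x, "year"), length(x)))
  cat(sprintf("  mean %.4g, sd %.4g, range [%.4g, %.4g]\n",
              mean(unclass(x)), sd(unclass(x)), min(x), max(x)))
  invisible(x)
}

# Copy series metadata from `from` onto numeric vector `values`.
as_series_like <- function(values, from) {
  structure(as.numeric(values),
            movie_id = attr(from, "movie_id"),
            year = attr(from, "year"),
            dimension = attr(from, "dimension"),
            class = "event_series")
}

#' Normalize an event series to mean 0, standard deviation 1
#'
#' Centering and scaling use the population standard deviation (divide by
#' n, not n - 1).  Both estimators in the package are scale and shift
#' invariant, so only consistency of the convention matters.  Metadata is
#' preserved; the operation is idempotent.
#'
#' @param x numeric vector or [event_series()].
#' @return normalized series of the same class.
#' @examples
#' normalize_series(c(1, 2, 3))   # -1.2247, 0, 1.2247
#' @export
normalize_series <- function(x) {
  v <- as.numeric(x)
  s <- sqrt(mean((v - mean(v))^2))
  if (!is.finite(s) || s <= 0) {
    stop("cannot normalize a degenerate (constant) series", call. = FALSE)
  }
  out <- (v - mean(v)) / s
  if (inherits(x, "event_series")) as_series_like(out, x) else out
}

is_normalized <- function(x, tol = 1e-9) {
  v <- as.numeric(x)
  abs(mean(v)) < tol && abs(sqrt(mean((v - mean(v))^2)) - 1) < tol
}
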