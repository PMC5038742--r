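#' Window maximum and minimum of a scalar trace
#'
#' Returns the global maximum and minimum of a scalar signal inside the
#' time window `[start, start + duration]`.  Ties are broken by the
#' earliest sample index.  All downstream step/fall features are functions
#' of these two extrema only.
#'
#' @param x numeric vector: the per-sample scalar trace.
#' @param start window start time in seconds.
#' @param duration window length in seconds.
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample (seconds), default 0.
#' @return A list with elements `max` and `min`, each a list
#'   `(index, time, value, kind)`.
#' @examples
#' w <- window_extrema(sin(2 * pi * (0:99) / 50), 0, 1.98, fs = 50)
#' w$max$time; w$min$time
#' @export
window_extrema <- function(x, start, duration, fs, t0 = 0) {
  n <- length(x)
  rg <- window_index_range(n, fs, t0, start, duration)
  idx <- rg[1]:rg[2]
  seg <- x[idx]
  imax <- idx[which.max(seg)]
  imin <- idx[which.min(seg)]
  mk <- function(i, kind) list(index = i, time = t0 + (i - 1) / fs, value = x[i], kind = kind)
  list(max = mk(imax, "max"), min = mk(imin, "min"))
}

#' Step features of an analysis window
#'
#' The two low-energy step features:
#' * `f1` (g): amplitude range of the vertical acceleration,
#'   max(Gz) - min(Gz) over the window;
#' * `f2` (s): signed time difference between the longitudinal maximum and
#'   the longitudinal minimum, t(max(Gy)) - t(min(Gy)).
#'
#' @param oriented a [project_components()] result.
#' @param start,duration window position and length in seconds.
#' @return A `step_features` list `(f1, f2, window_start)`.
#' @export
step_features <- function(oriented, start, duration) {
  stopifnot(inherits(oriented, "oriented_series"))
  wv <- window_extrema(oriented$vertical, start, duration, oriented$fs, oriented$t0)
  wl <- window_extrema(oriented$longitudinal, start, duration, oriented$fs, oriented$t0)
  structure(list(f1 = wv$max$value - wv$min$value,
                 f2 = wl$max$time - wl$min$time,
                 window_start = start),
            class = "step_features")
}

#' Fall-detection features of an analysis window
#'
#' Computed on the acceleration magnitude |G|:
#' * `f1` (g): amplitude range, max(|G|) - min(|G|) -- the impact spike
#'   above the free-fall dip;
#' * `f2` (ms): absolute elapsed time between the window minimum and the
#'   window maximum of |G| -- the descent-to-impact duration.
#'
#' @inheritParams step_features
#' @return A `fall_features` list `(f1, f2, window_start)`.
#' @export
fall_features <- function(oriented, start, duration) {
  stopifnot(inherits(oriented, "oriented_series"))
  w <- window_extrema(oriented$magnitude, start, duration, oriented$fs, oriented$t0)
  structure(list(f1 = w$max$value - w$min$value,
                 f2 = abs(w$max$time - w$min$time) * 1000,
                 window_start = start),
            class = "fall_features")
}

#' Fall-classification features at the impact peak
#'
#' The raw device-axis values (Gx, Gy, Gz), in g, at the sample where |G|
#' attains its maximum inside the window (earliest index on ties).  Under
#' impact the raw axes carry the body orientation at ground contact, which
#' separates frontal-walking, frontal-sitting and other falls.
#'
#' @param series the raw [accel_series()].
#' @param oriented the matching [project_components()] result.
#' @param start,duration window position and length in seconds.
#' @return A `fall_class_features` list `(f1, f2, f3)` = (Gx, Gy, Gz) at
#'   the impact peak.
#' @export
fall_class_features <- function(series, oriented, start, duration) {
  stopifnot(inherits(series, "accel_series"), inherits(oriented, "oriented_series"))
  w <- window_extrema(oriented$magnitude, start, duration, oriented$fs, oriented$t0)
  v <- series$xyz[w$max$index, ]
  structure(list(f1 = unname(v[1]), f2 = unname(v[2]), f3 = unname(v[3]),
                 index = w$max$index, time = w$max$time),
            class = "fall_class_features")
}
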