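#' Uniformly sampled tri-axial acceleration series
#'
#' The universal input container: an ordered set of (ax, ay, az) samples in
#' g units (1 g = 9.80665 m/s^2), sampled at a constant rate `fs` starting
#' at time `t0`.  Sample `k` (1-based) has time `t0 + (k - 1) / fs`.
#'
#' @param xyz numeric matrix with 3 columns (ax, ay, az) or a 3-column
#'   data.frame; one row per sample, values in g.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @return An object of class `accel_series` with fields `xyz`, `fs`, `t0`.
#' @examples
#' s <- accel_series(cbind(0, 0, rep(1, 100)), fs = 50)
#' series_times(s)[1:3]
#' @export
accel_series <- function(xyz, fs, t0 = 0) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stopf("accel_series needs 3 columns (ax, ay, az), got %d", ncol(xyz))
  if (nrow(xyz) < 1L) stopf("accel_series needs at least one sample")
  storage.mode(xyz) <- "double"
  if (!all(is.finite(xyz))) stopf("accel_series: all components must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stopf("accel_series: fs must be a single positive number")
  colnames(xyz) <- c("ax", "ay", "az")
  structure(list(xyz = xyz, fs = as.numeric(fs), t0 = as.numeric(t0)),
            class = "accel_series")
}

#' @export
print.accel_series <- function(x, ...) {
  cat(sprintf("<accel_series> %d samples @ %g Hz, t0 = %g s (%.2f s)\n",
              nrow(x$xyz), x$fs, x$t0, (nrow(x$xyz) - 1) / x$fs))
  invisible(x)
}

#' @export
length.accel_series <- function(x) nrow(x$xyz)

#' Sample times of a series
#'
#' @param x an `accel_series`, `gravity_series` or `oriented_series`.
#' @return Numeric vector of sample times in seconds.
#' @export
series_times <- function(x) x$t0 + (seq_len(series_n(x)) - 1) / x$fs

series_n <- function(x) {
  if (!is.null(x$xyz)) nrow(x$xyz) else length(x$vertical)
}

# Index range of the window [start, start + duration] on the sample grid.
window_index_range <- function(n, fs, t0, start, duration) {
  eps <- 1e-9
  i1 <- ceiling((start - t0) * fs - eps) + 1
  i2 <- floor((start + duration - t0) * fs + eps) + 1
  if (i1 < 1 || i2 > n)
    stopf("window [%g, %g] s lies outside the signal extent [%g, %g] s",
          start, start + duration, t0, t0 + (n - 1) / fs)
  if (i2 - i1 + 1 < 2)
    stopf("window [%g, %g] s contains fewer than 2 samples", start, start + duration)
  c(as.integer(i1), as.integer(i2))
}

#' Estimate the gravity component by centred moving average
#'
#' Gravity (plus any slow drift in sensor placement) is the quasi-static
#' part of the acceleration.  It is estimated per axis as the centred
#' moving average over a `window_s`-second window (2 s by default),
#' truncated at the edges of the recording: the estimate at sample `k` is
#' the mean of all samples within `window_s / 2` seconds of `k`'s time.
#'
#' @param series an [accel_series()].
#' @param window_s averaging window length in seconds (> 0), default 2.
#' @return A `gravity_series`: per-sample gravity estimate triples plus the
#'   `window_s` used; same length, `fs` and `t0` as the input.
#' @export
estimate_gravity <- function(series, window_s = 2.0) {
  stopifnot(inherits(series, "accel_series"))
  if (!is.numeric(window_s) || length(window_s) != 1L || !is.finite(window_s) || window_s <= 0)
    stopf("estimate_gravity: window_s must be a single positive number")
  x <- series$xyz
  n <- nrow(x)
  h <- floor(window_s / 2 * series$fs + 1e-9)   # half-window in samples
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  cs <- rbind(0, apply(x, 2, cumsum))
  g <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  colnames(g) <- c("gx", "gy", "gz")
  structure(list(xyz = g, window_s = window_s, fs = series$fs, t0 = series$t0),
            class = "gravity_series")
}

#' Project a series onto gravity-aligned movement components
#'
#' Decomposes each sample against the per-sample gravity estimate:
#' * `vertical`: projection onto the gravity direction minus the gravity
#'   magnitude -- the dynamic vertical acceleration, 0 for a motionless
#'   sensor;
#' * `longitudinal`: the gravity-orthogonal residual projected onto the
#'   dominant horizontal direction, taken as the first principal axis of
#'   the horizontal residuals over the whole recording, with its sign fixed
#'   so that the mean cubed projection is non-negative (a deterministic,
#'   orientation-free proxy for the movement direction);
#' * `magnitude`: the Euclidean norm |G| of each raw sample.
#'
#' @param series an [accel_series()].
#' @param gravity matching [estimate_gravity()] output (same length).
#' @return An `oriented_series` with fields `vertical`, `longitudinal`,
#'   `magnitude` (numeric vectors, g units), `axis` (the unit horizontal
#'   direction used), `fs`, `t0`.
#' @export
project_components <- function(series, gravity) {
  stopifnot(inherits(series, "accel_series"), inherits(gravity, "gravity_series"))
  x <- series$xyz
  g <- gravity$xyz
  if (nrow(x) != nrow(g)) stopf("series and gravity have different lengths (%d vs %d)", nrow(x), nrow(g))
  gn <- sqrt(rowSums(g^2))
  if (any(gn < 1e-9))
    stopf("degenerate orientation: gravity estimate has (near-)zero norm at sample %d",
          which(gn < 1e-9)[1])
  u <- g / gn
  proj <- rowSums(x * u)
  vertical <- proj - gn
  resid <- x - u * proj
  # dominant horizontal direction: first right singular vector of the
  # residual cloud; degenerate (motionless) clouds give a zero trace
  sv <- svd(resid, nu = 0, nv = 3)
  if (sv$d[1] < 1e-12 * sqrt(nrow(x))) {
    axis <- c(0, 0, 0)
    longitudinal <- numeric(nrow(x))
  } else {
    axis <- sv$v[, 1]
    longitudinal <- drop(resid %*% axis)
    s3 <- mean(longitudinal^3)
    if (s3 < 0 || (s3 == 0 && {
      nz <- which(abs(axis) > 1e-12)[1]
      length(nz) == 1L && !is.na(nz) && axis[nz] < 0
    })) {
      axis <- -axis
      longitudinal <- -longitudinal
    }
  }
  structure(list(vertical = vertical, longitudinal = longitudinal,
                 magnitude = sqrt(rowSums(x^2)), axis = axis,
                 fs = series$fs, t0 = series$t0),
            class = "oriented_series")
}

#' Torso-location amplitude calibration
#'
#' Walking accelerations at the lower and upper torso differ slightly in
#' amplitude.  The calibration stores the per-axis signal standard
#' deviations measured at each location; [compensate_location()] rescales a
#' recording from one location's amplitude regime to the other's.
#'
#' The published calibration covers the y (movement) and z (vertical) axes
#' at 60 steps/min; no x-axis figure is given, so the default keeps x
#' unscaled (equal entries at both locations).
#'
#' @param lower,upper named numeric vectors `c(ax=, ay=, az=)` of standard
#'   deviations in g; all entries > 0.
#' @return A `location_calibration` object.
#' @export
location_calibration <- function(lower, upper) {
  chk <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 3L || !all(is.finite(v)) || any(v <= 0))
      stopf("location_calibration: '%s' must be 3 positive numbers (ax, ay, az)", nm)
    v <- as.numeric(v); names(v) <- c("ax", "ay", "az"); v
  }
  structure(list(lower_torso = chk(lower, "lower"), upper_torso = chk(upper, "upper")),
            class = "location_calibration")
}

#' Default torso calibration from the published table
#'
#' y/z standard deviations at 60 steps/min: lower torso (0.0794, 0.0830) g,
#' upper torso (0.0848, 0.0862) g; x is not tabulated and is left unscaled.
#'
#' @return A [location_calibration()].
#' @export
default_location_calibration <- function() {
  location_calibration(lower = c(ax = 1, ay = 0.0794, az = 0.0830),
                       upper = c(ax = 1, ay = 0.0848, az = 0.0862))
}

#' Rescale a recording between torso locations
#'
#' Each axis is scaled about its own series mean by the ratio of the
#' calibration standard deviations (target / source), so the quasi-static
#' gravity offset is preserved while the dynamic amplitude is mapped to the
#' target location's regime.  `from_loc == to_loc` is the identity.
#'
#' @param series an [accel_series()].
#' @param cal a [location_calibration()].
#' @param from_loc,to_loc `"lower_torso"` or `"upper_torso"`.
#' @return A rescaled [accel_series()].
#' @export
compensate_location <- function(series, cal = default_location_calibration(),
                                from_loc, to_loc) {
  stopifnot(inherits(series, "accel_series"), inherits(cal, "location_calibration"))
  locs <- c("lower_torso", "upper_torso")
  from_loc <- match.arg(from_loc, locs)
  to_loc <- match.arg(to_loc, locs)
  if (from_loc == to_loc) return(series)
  ratio <- cal[[to_loc]] / cal[[from_loc]]
  x <- series$xyz
  mu <- colMeans(x)
  out <- sweep(sweep(x, 2, mu, "-"), 2, ratio, "*")
  out <- sweep(out, 2, mu, "+")
  accel_series(out, fs = series$fs, t0 = series$t0)
}
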