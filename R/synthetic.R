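#' @name stepfall-synthetic
#' @title Synthetic accelerometer traces
#' @description
#' Seeded generators of labelled tri-axial traces -- walks, falls and null
#' activities -- whose extracted window features follow the published model
#' distributions.  Waveform shapes (raised-cosine pulses for steps, a
#' free-fall dip followed by an impact spike for falls) are a package
#' construction: the movements are defined only through their window
#' extrema features, which is exactly what the generators control.
NULL

#' Walk generation parameters
#'
#' Defaults mirror the training protocol behind the published tables:
#' 20 metronome-paced steps at 80 steps/min from a lower-torso sensor.
#'
#' @param cadence steps per minute (> 0).
#' @param n_steps number of steps (>= 1).
#' @param fs sampling rate in Hz (>= 20).
#' @param noise_sd white sensor noise standard deviation in g
#'   (default 0.02, a typical consumer accelerometer at rest).
#' @param location `"lower_torso"` or `"upper_torso"`.
#' @param seed RNG seed.
#' @return A `walk_spec` list.
#' @export
walk_spec <- function(cadence = 80, n_steps = 20, fs = 50, noise_sd = 0.02,
                      location = c("lower_torso", "upper_torso"), seed = 1) {
  if (cadence <= 0) stopf("walk_spec: cadence must be > 0")
  if (n_steps < 1) stopf("walk_spec: n_steps must be >= 1")
  if (fs < 20) stopf("walk_spec: fs must be >= 20 Hz")
  structure(list(cadence = cadence, n_steps = as.integer(n_steps), fs = fs,
                 noise_sd = noise_sd, location = match.arg(location),
                 seed = as.integer(seed)),
            class = "walk_spec")
}

#' Fall generation parameters
#'
#' @param class_label fall class: `"c1"` (frontal, walking), `"c2"`
#'   (frontal, sitting) or `"c3"` (other).
#' @param fs sampling rate in Hz (default 100; impact timing is on the
#'   millisecond scale).
#' @param pre_s,post_s context seconds before and after the fall.
#' @param context `"quiet"` or `"walking"` surroundings.
#' @param trunc_class truncation (in sigmas) of the per-class impact-axis
#'   draws; default 0.5.  0 draws the class means exactly.
#' @param trunc_f2 truncation (in sigmas) of the fall-timing draw; default
#'   1, which guarantees detectability at the default threshold.
#' @param seed RNG seed.
#' @return A `fall_spec` list.
#' @export
fall_spec <- function(class_label = c("c1", "c2", "c3"), fs = 100,
                      pre_s = 3, post_s = 3, context = c("quiet", "walking"),
                      trunc_class = 0.5, trunc_f2 = 1, seed = 1) {
  structure(list(class_label = match.arg(class_label), fs = fs,
                 pre_s = pre_s, post_s = post_s, context = match.arg(context),
                 trunc_class = trunc_class, trunc_f2 = trunc_f2,
                 seed = as.integer(seed)),
            class = "fall_spec")
}

# (lambda, sigma) for both step features at an arbitrary cadence: linear
# interpolation over the trained 60/80/100 grid, clamped at the ends.
interp_step_params <- function(cadence) {
  tb <- step_table()
  grid <- as.numeric(rownames(tb$f1))
  g <- function(m, col) approx(grid, m[, col], xout = cadence, rule = 2)$y
  list(f1 = c(lambda = g(tb$f1, 1), sigma = g(tb$f1, 2)),
       f2 = c(lambda = g(tb$f2, 1), sigma = g(tb$f2, 2)))
}

# Raised-cosine (Hann) lobe of full width w centred at c, evaluated at t.
hann_lobe <- function(t, c, w) {
  ifelse(abs(t - c) < w / 2, 0.5 * (1 + cos(2 * pi * (t - c) / w)), 0)
}

# Biphasic zero-mean pulse 2 sin^3(x) cos(x), x = pi*(t-t_on)/d on [0, d]:
# maximum 3*sqrt(3)/8 at x = pi/3, minimum -3*sqrt(3)/8 at x = 2*pi/3.
BIPHASIC_PEAK <- 3 * sqrt(3) / 8
biphasic_pulse <- function(t, t_on, d) {
  x <- pi * (t - t_on) / d
  ifelse(x > 0 & x < pi, 2 * sin(x)^3 * cos(x), 0)
}

#' Generate a synthetic walking trace
#'
#' Each step draws its target features (f1*, f2*) from the cadence's
#' Gaussian distributions (published parameters at 60/80/100 steps/min,
#' linearly interpolated in between).  The vertical trace carries one
#' biphasic raised-cosine pulse per step whose max - min equals f1* and
#' whose maximum marks the ground-truth step time; the longitudinal trace
#' carries an unequal-lobe doublet whose maximum and minimum are separated
#' by f2* (signed).  Steps are spaced at the cadence interval with +/- 3 %
#' timing jitter.  Gravity (0, 0, 1) g, white noise of `noise_sd` and the
#' torso-location amplitude ratios are then applied.  Draws whose f2*
#' cannot be realised on the sample grid (below ~2.5 sample periods or
#' beyond 40 % of the step period) are redrawn, up to 100 attempts.
#'
#' @param spec a [walk_spec()].
#' @return List with `series` (an [accel_series()]), `step_times`
#'   (ground-truth step times, s) and `targets` (data.frame of the drawn
#'   f1*, f2* per step).  Bit-identical for identical specs.
#' @export
synth_walk <- function(spec = walk_spec()) {
  stopifnot(inherits(spec, "walk_spec"))
  with_seed(spec$seed, {
    period <- 60 / spec$cadence
    pars <- interp_step_params(spec$cadence)
    pad <- 2.0                                 # quiet margin for the gravity window

    step_t <- numeric(spec$n_steps)
    step_t[1] <- pad
    if (spec$n_steps > 1)
      for (i in 2:spec$n_steps)
        step_t[i] <- step_t[i - 1] + period * (1 + runif(1, -0.03, 0.03))

    f2_lo <- 2.5 / spec$fs
    f2_hi <- 0.4 * period
    draw1 <- function() {
      for (a in 1:100) {
        v <- rnorm(1, pars$f1["lambda"], pars$f1["sigma"])
        if (v > 0.05) return(v)
      }
      stopf("synth_walk: could not draw a positive f1 in 100 attempts")
    }
    draw2 <- function() {
      for (a in 1:100) {
        v <- rnorm(1, pars$f2["lambda"], pars$f2["sigma"])
        if (abs(v) >= f2_lo && abs(v) <= f2_hi) return(v)
      }
      stopf("synth_walk: could not draw a feasible f2 in 100 attempts")
    }
    f1s <- vapply(seq_len(spec$n_steps), function(i) draw1(), 0)
    f2s <- vapply(seq_len(spec$n_steps), function(i) draw2(), 0)

    # snap step anchors to the sample grid so the generated extrema land
    # exactly on samples and the drawn features are reproduced exactly
    step_t <- round(step_t * spec$fs) / spec$fs
    f2s <- round(f2s * spec$fs) / spec$fs
    f2s <- ifelse(abs(f2s) < 2 / spec$fs, sign(f2s) * 2 / spec$fs, f2s)

    total <- step_t[spec$n_steps] + pad
    t <- seq(0, total, by = 1 / spec$fs)
    vert <- numeric(length(t))
    long <- numeric(length(t))
    d <- min(0.5 * period, 0.4)                # vertical pulse duration
    for (i in seq_len(spec$n_steps)) {
      pulse <- biphasic_pulse(t, step_t[i] - d / 3, d)
      rng <- max(pulse) - min(pulse)
      vert <- vert + pulse * (f1s[i] / rng)    # sampled max - min == f1*
      # longitudinal doublet: taller-narrower positive lobe, shorter-wider
      # negative lobe of equal area (zero mean, positive skewness)
      a <- 0.35 * f1s[i]
      w <- max(2 / spec$fs, min(0.7 * abs(f2s[i]), 0.3 * period))
      c_min <- step_t[i] - round(f2s[i] / 2 * spec$fs) / spec$fs
      long <- long - 0.8 * a * hann_lobe(t, c_min, 1.5 * w) +
        1.2 * a * hann_lobe(t, c_min + f2s[i], w)
    }

    dyn <- cbind(ax = 0, ay = long, az = vert)
    if (spec$location == "upper_torso") {
      cal <- default_location_calibration()
      dyn <- sweep(dyn, 2, cal$upper_torso / cal$lower_torso, "*")
    }
    xyz <- dyn + matrix(rnorm(3 * length(t), 0, spec$noise_sd), ncol = 3)
    xyz[, 3] <- xyz[, 3] + 1                   # gravity baseline (0, 0, 1) g

    list(series = accel_series(xyz, fs = spec$fs, t0 = 0),
         step_times = step_t,
         targets = data.frame(step = seq_len(spec$n_steps), f1 = f1s, f2 = f2s))
  })
}

# Truncated-normal draw by rejection, truncation at +/- k*sigma.
rtrunc_norm <- function(n, lambda, sigma, k) {
  if (k <= 0) return(rep(lambda, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- rnorm(1, lambda, sigma)
      if (abs(v - lambda) <= k * sigma) break
    }
    out[i] <- v
  }
  out
}

#' Generate a synthetic fall trace
#'
#' Builds an acceleration-magnitude profile with a free-fall dip (to
#' 0.1 g) followed by an impact spike, embedded in quiet or walking
#' context.  The dip-to-spike elapsed time is drawn from the published
#' fall f2 distribution truncated at +/- 1 sigma (so every generated fall
#' satisfies the 2 ln 10 detectability criterion at tau2 = 0.1).  The raw
#' axis triple at the impact sample is drawn from the requested class's
#' published feature distributions truncated at +/- 0.5 sigma; the impact
#' peak height is the norm of that triple, so the classification features
#' are reproduced exactly and the implied |G| range lands inside the
#' +/- 1 sigma band of the published fall f1 distribution.
#'
#' @param spec a [fall_spec()].
#' @return List with `series`, `fall_time` (impact time, s), `class_label`,
#'   `impact_triple` (the drawn (Gx, Gy, Gz) at impact) and `targets`
#'   (drawn fall f2 in ms and implied f1 in g).
#' @export
synth_fall <- function(spec = fall_spec()) {
  stopifnot(inherits(spec, "fall_spec"))
  with_seed(spec$seed, {
    ctab <- fall_class_table()[[spec$class_label]]
    ftab <- fall_table()
    triple <- vapply(ctab, function(p) rtrunc_norm(1, p[1], p[2], spec$trunc_class), 0)
    m_max <- sqrt(sum(triple^2))
    m_min <- 0.1
    f2_ms <- rtrunc_norm(1, ftab$f2[1], ftab$f2[2], spec$trunc_f2)
    delta <- f2_ms / 1000

    fall_len <- 1.0
    # context before/after the 1-s fall segment
    mk_context <- function(dur, sub_seed) {
      if (spec$context == "quiet") {
        n <- round(dur * spec$fs)
        cbind(rnorm(n, 0, 0.005), rnorm(n, 0, 0.005), 1 + rnorm(n, 0, 0.005))
      } else {
        w <- synth_walk(walk_spec(cadence = 80,
                                  n_steps = max(1L, floor((dur - 4) / 0.75)),
                                  fs = spec$fs, seed = sub_seed))
        x <- w$series$xyz
        n <- round(dur * spec$fs)
        if (nrow(x) >= n) x[seq_len(n), , drop = FALSE]
        else rbind(x, matrix(rep(c(0, 0, 1), each = n - nrow(x)), ncol = 3))
      }
    }
    sub_seeds <- sample.int(2^30, 2)
    pre <- mk_context(spec$pre_s, sub_seeds[1])
    post <- mk_context(spec$post_s, sub_seeds[2])

    n_fall <- round(fall_len * spec$fs) + 1
    tf <- (seq_len(n_fall) - 1) / spec$fs
    t_min <- 0.35
    t_max <- t_min + delta
    mag <- 1 - (1 - m_min) * hann_lobe(tf, t_min, delta) +
      (m_max - 1) * hann_lobe(tf, t_max, delta)
    # snap the impact so the sampled peak equals m_max exactly
    k_max <- which.min(abs(tf - t_max))
    mag[k_max] <- m_max
    k_min <- which.min(abs(tf - t_min))
    mag[k_min] <- m_min
    alpha <- hann_lobe(tf, tf[k_max], delta)
    alpha[k_max] <- 1
    zhat <- c(0, 0, 1)
    vhat <- triple / m_max
    dirs <- outer(1 - alpha, zhat) + outer(alpha, vhat)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    seg <- dirs * mag
    seg[k_max, ] <- triple                    # exact impact components

    xyz <- rbind(pre, seg, post)
    series <- accel_series(xyz, fs = spec$fs, t0 = 0)
    list(series = series,
         fall_time = nrow(pre) / spec$fs + tf[k_max],
         class_label = spec$class_label,
         impact_triple = triple,
         targets = data.frame(f1 = m_max - m_min, f2_ms = f2_ms))
  })
}

#' Generate a null-activity trace
#'
#' Gravity baseline (0, 0, 1) g plus seeded noise: slow AR(1)-coloured
#' noise for the sitting (sd 0.012 g) and standing (sd 0.008 g)
#' archetypes, broadband white noise (sd 0.05 g) for the generic noise
#' archetype.
#'
#' @param archetype `"sitting"`, `"standing"` or `"noise"`.
#' @param duration seconds (> 0).
#' @param fs sampling rate in Hz.
#' @param seed RNG seed.
#' @return An [accel_series()].
#' @export
synth_null <- function(archetype = c("sitting", "standing", "noise"),
                       duration = 30, fs = 50, seed = 1) {
  archetype <- match.arg(archetype)
  if (duration <= 0) stopf("synth_null: duration must be > 0")
  with_seed(seed, {
    n <- round(duration * fs) + 1
    coloured <- function(sd_target) {
      e <- matrix(rnorm(3 * n), ncol = 3)
      x <- apply(e, 2, function(col) as.numeric(stats::filter(col, 0.95, method = "recursive")))
      x * sd_target / sqrt(1 / (1 - 0.95^2))   # stationary AR(1) variance
    }
    noise <- switch(archetype,
                    sitting = coloured(0.012),
                    standing = coloured(0.008),
                    noise = matrix(rnorm(3 * n, 0, 0.05), ncol = 3))
    noise[, 3] <- noise[, 3] + 1
    accel_series(noise, fs = fs, t0 = 0)
  })
}

#' Seeded Gaussian feature draws
#'
#' Reproducible i.i.d. Gaussian draws, used to exercise parameter-recovery
#' round trips against the published tables.
#'
#' @param lambda mean.
#' @param sigma standard deviation (> 0).
#' @param n number of draws (>= 1).
#' @param seed RNG seed.
#' @return Numeric vector of `n` draws.
#' @export
draw_features <- function(lambda, sigma, n, seed = 1) {
  if (sigma <= 0) stopf("draw_features: sigma must be > 0")
  if (n < 1) stopf("draw_features: n must be >= 1")
  with_seed(seed, rnorm(n, lambda, sigma))
}
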