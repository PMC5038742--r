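#' @name stepfall-models
#' @title Stochastic movement models
#' @description
#' Per-cadence Gaussian likelihoods for the step features, a two-sided
#' exponential null-class model, a Bayesian posterior over cadences, and
#' kernel-product models for fall detection and classification.
#'
#' The published training tables (abdomen-worn sensor, three male and
#' three female participants, 20 metronome-paced steps per cadence; 30
#' recorded falls for the fall models) provide the default parameters:
#'
#' Step f1 (vertical range, g): 60 steps/min (0.4846, 0.2023);
#' 80 (0.6760, 0.2922); 100 (0.8141, 0.3581).
#' Step f2 (longitudinal max-min time, s): 60 (0.1440, 0.0826);
#' 80 (0.1188, 0.0715); 100 (0.0688, 0.0370).
#' Fall f1 (|G| range, g): (7.8549, 2.5692); fall f2 (min-to-max time, ms):
#' (136.27, 81.36); detection threshold tau2 = 0.1.
#' Fall classes (Gx, Gy, Gz at impact, g): c1 frontal fall when walking
#' (5.2423, 2.0798), (1.9998, 1.0555), (-1.8940, 0.2080); c2 frontal fall
#' when sitting (5.1299, 2.0878), (-0.8582, 3.8089), (-3.9783, 0.1520);
#' c3 other fall (7.1742, 1.4663), (1.4240, 4.1176), (0.0463, 3.8780).
NULL

SIGMA_FLOOR <- 1e-6

# ---- constructors -----------------------------------------------------

#' Per-cadence Gaussian feature model
#'
#' @param mu_label cadence label in steps/min.
#' @param f1,f2 numeric `c(lambda, sigma)`: mean and standard deviation of
#'   the feature at this cadence (f1 in g, f2 in s); `sigma > 0`.
#' @return A `speed_gaussian` object.
#' @export
speed_gaussian <- function(mu_label, f1, f2) {
  chk <- function(p, nm) {
    if (!is.numeric(p) || length(p) != 2L || !all(is.finite(p)) || p[2] <= 0)
      stopf("speed_gaussian: '%s' must be c(lambda, sigma) with sigma > 0", nm)
    list(lambda = as.numeric(p[1]), sigma = as.numeric(p[2]))
  }
  structure(list(mu_label = as.numeric(mu_label), f1 = chk(f1, "f1"), f2 = chk(f2, "f2")),
            class = "speed_gaussian")
}

#' Two-sided exponential null-class parameters for one feature
#'
#' The null (no movement) class is modelled by two outward exponential
#' tails: an upward tail of rate `lambda01` anchored at `mu01` and a
#' downward tail of rate `lambda02` anchored at `mu02 <= mu01`, with the
#' inter-anchor plateau taking the larger tail boundary value; the whole
#' density is normalised to unit mass (see [null_density()]).
#'
#' @param lambda01,mu01 upward tail rate (> 0) and anchor.
#' @param lambda02,mu02 downward tail rate (> 0) and anchor (`mu02 <= mu01`).
#' @return A `null_feature` parameter list.
#' @export
null_feature <- function(lambda01, mu01, lambda02, mu02) {
  if (lambda01 <= 0 || lambda02 <= 0) stopf("null_feature: rates must be > 0")
  if (mu02 > mu01) stopf("null_feature: mu02 must be <= mu01")
  structure(list(lambda01 = as.numeric(lambda01), mu01 = as.numeric(mu01),
                 lambda02 = as.numeric(lambda02), mu02 = as.numeric(mu02)),
            class = "null_feature")
}

#' Full per-cadence model set
#'
#' @param speeds list of [speed_gaussian()] objects (default cadence grid
#'   60, 80, 100 steps/min).
#' @param null list with elements `f1` and `f2`, each a [null_feature()].
#' @param prior named non-negative vector summing to 1 over
#'   `c("null", <cadence labels>)`; default uniform.
#' @param delta_max analysis window length (s) the set was trained with.
#' @return A `speed_model_set`.
#' @export
speed_model_set <- function(speeds, null, prior = NULL, delta_max = 0.9) {
  stopifnot(is.list(speeds), length(speeds) >= 1L)
  lapply(speeds, function(s) stopifnot(inherits(s, "speed_gaussian")))
  stopifnot(inherits(null$f1, "null_feature"), inherits(null$f2, "null_feature"))
  labels <- vapply(speeds, function(s) format(s$mu_label), "")
  names(speeds) <- labels
  classes <- c("null", labels)
  if (is.null(prior)) {
    prior <- rep(1 / length(classes), length(classes))
    names(prior) <- classes
  }
  if (!all(classes %in% names(prior)))
    stopf("prior must be named over: %s", paste(classes, collapse = ", "))
  prior <- prior[classes]
  if (any(prior < 0) || abs(sum(prior) - 1) > 1e-9)
    stopf("prior entries must be >= 0 and sum to 1")
  structure(list(speeds = speeds, null = null, prior = prior,
                 delta_max = as.numeric(delta_max)),
            class = "speed_model_set")
}

#' Fall-detection model
#'
#' @param f1,f2 numeric `c(lambda, sigma)` for the fall features (f1 in g,
#'   f2 in ms).
#' @param tau2 detection threshold on the kernel product, in (0, 1);
#'   default 0.1.
#' @return A `fall_model`.
#' @export
fall_model <- function(f1, f2, tau2 = 0.1) {
  chk <- function(p, nm) {
    if (!is.numeric(p) || length(p) != 2L || p[2] <= 0)
      stopf("fall_model: '%s' must be c(lambda, sigma) with sigma > 0", nm)
    list(lambda = as.numeric(p[1]), sigma = as.numeric(p[2]))
  }
  if (tau2 <= 0 || tau2 >= 1) stopf("fall_model: tau2 must be in (0, 1)")
  structure(list(f1 = chk(f1, "f1"), f2 = chk(f2, "f2"), tau2 = as.numeric(tau2)),
            class = "fall_model")
}

#' Fall-classification model
#'
#' @param classes named list over exactly `c1`, `c2`, `c3`; each element a
#'   list with `f1`, `f2`, `f3`, each `c(lambda, sigma)` (g units).
#' @param tau optional named per-class score thresholds; classes scoring
#'   below their threshold are excluded and `c3` ("other fall") is the
#'   fallback.
#' @return A `fall_class_model`.  Class labels: c1 = frontal fall when
#'   walking, c2 = frontal fall when sitting, c3 = other fall.
#' @export
fall_class_model <- function(classes, tau = NULL) {
  if (!identical(names(classes), c("c1", "c2", "c3")))
    stopf("fall_class_model: classes must be named c1, c2, c3 in order")
  classes <- lapply(classes, function(cl) {
    lapply(cl[c("f1", "f2", "f3")], function(p) {
      if (!is.numeric(p) || length(p) != 2L || p[2] <= 0)
        stopf("fall_class_model: each feature needs c(lambda, sigma), sigma > 0")
      list(lambda = as.numeric(p[1]), sigma = as.numeric(p[2]))
    })
  })
  if (!is.null(tau)) {
    if (!all(names(tau) %in% names(classes))) stopf("fall_class_model: tau names must be class labels")
    tau <- as.numeric(tau[names(classes)])
    names(tau) <- names(classes)
  }
  structure(list(classes = classes, tau = tau,
                 labels = c(c1 = "frontal fall when walking",
                            c2 = "frontal fall when sitting",
                            c3 = "other fall")),
            class = "fall_class_model")
}

# ---- published defaults ----------------------------------------------

step_table <- function() {
  list(
    f1 = rbind(`60` = c(0.4846, 0.2023), `80` = c(0.6760, 0.2922), `100` = c(0.8141, 0.3581)),
    f2 = rbind(`60` = c(0.1440, 0.0826), `80` = c(0.1188, 0.0715), `100` = c(0.0688, 0.0370))
  )
}

fall_table <- function() list(f1 = c(7.8549, 2.5692), f2 = c(136.27, 81.36))

fall_class_table <- function() {
  list(c1 = list(f1 = c(5.2423, 2.0798), f2 = c(1.9998, 1.0555), f3 = c(-1.8940, 0.2080)),
       c2 = list(f1 = c(5.1299, 2.0878), f2 = c(-0.8582, 3.8089), f3 = c(-3.9783, 0.1520)),
       c3 = list(f1 = c(7.1742, 1.4663), f2 = c(1.4240, 4.1176), f3 = c(0.0463, 3.8780)))
}

# Default null-class parameters.  Not published; chosen once for a
# torso-worn sensor at rest or in non-gait motion: the f1 null mass sits on
# small vertical ranges (noise-driven, < ~0.12 g) with a fast upward tail,
# and the f2 null mass is symmetric and wide (extrema timing of noise is
# arbitrary within the window).
default_null_model <- function() {
  list(f1 = null_feature(lambda01 = 25, mu01 = 0.12, lambda02 = 120, mu02 = 0.01),
       f2 = null_feature(lambda01 = 8, mu01 = 0.40, lambda02 = 8, mu02 = -0.40))
}

#' Default cadence model set from the published training tables
#'
#' Cadence grid 60/80/100 steps/min with the published (lambda, sigma) per
#' feature, the default null-class model, and a uniform prior over
#' \{null, 60, 80, 100\}.
#'
#' @param prior optional named prior overriding the uniform default.
#' @return A [speed_model_set()].
#' @export
default_speed_model <- function(prior = NULL) {
  tb <- step_table()
  speeds <- lapply(rownames(tb$f1), function(r)
    speed_gaussian(as.numeric(r), f1 = tb$f1[r, ], f2 = tb$f2[r, ]))
  speed_model_set(speeds, default_null_model(), prior = prior)
}

#' Default fall-detection model from the published table
#' @return A [fall_model()] with tau2 = 0.1.
#' @export
default_fall_model <- function() {
  tb <- fall_table()
  fall_model(f1 = tb$f1, f2 = tb$f2, tau2 = 0.1)
}

#' Default fall-classification model from the published table
#' @return A [fall_class_model()] (argmax rule, no per-class thresholds).
#' @export
default_fall_class_model <- function() fall_class_model(fall_class_table())

# ---- fitting ----------------------------------------------------------

#' Fit a Gaussian feature model
#'
#' Sample mean and (n-1)-denominator standard deviation, with the standard
#' deviation floored at 1e-6 so constant inputs never produce a degenerate
#' likelihood.
#'
#' @param samples numeric vector of feature values (length >= 2).
#' @return `c(lambda = mean, sigma = sd)`.
#' @export
fit_gaussian <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stopf("fit_gaussian needs at least 2 samples")
  if (!all(is.finite(samples))) stopf("fit_gaussian: samples must be finite")
  c(lambda = mean(samples), sigma = max(sd(samples), SIGMA_FLOOR))
}

#' Fit the two-sided exponential null model for one feature
#'
#' Method of moments on the quartile tails: the anchors are the upper and
#' lower sample quartiles, and each tail rate is the reciprocal of the mean
#' excess beyond its anchor.  If no sample lies beyond an anchor the rate
#' falls back to `1 / sd(samples)`.
#'
#' @param samples numeric vector (length >= 4).
#' @return A [null_feature()].
#' @export
fit_null <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 4L) stopf("fit_null needs at least 4 samples")
  q <- quantile(samples, c(0.25, 0.75), names = FALSE)
  s <- max(sd(samples), SIGMA_FLOOR)
  up <- samples[samples > q[2]] - q[2]
  dn <- q[1] - samples[samples < q[1]]
  l01 <- if (length(up) && mean(up) > 0) 1 / mean(up) else 1 / s
  l02 <- if (length(dn) && mean(dn) > 0) 1 / mean(dn) else 1 / s
  null_feature(lambda01 = l01, mu01 = q[2], lambda02 = l02, mu02 = q[1])
}

#' Null-class density
#'
#' Evaluates the two-sided exponential null density: upward tail for
#' `f >= mu01`, downward tail for `f <= mu02`, and a plateau at the larger
#' tail boundary value in between; the total is normalised to unit mass
#' (each tail alone carries mass 1/2 before normalisation, so the
#' normaliser is `1 + (mu01 - mu02) * max(lambda01, lambda02) / 2`).
#'
#' @param f numeric vector of feature values.
#' @param p a [null_feature()].
#' @param log if `TRUE`, return the log density.
#' @return Density values (vectorised over `f`).
#' @export
null_density <- function(f, p, log = FALSE) {
  stopifnot(inherits(p, "null_feature"))
  z <- 1 + (p$mu01 - p$mu02) * max(p$lambda01, p$lambda02) / 2
  d <- ifelse(f >= p$mu01,
              p$lambda01 / 2 * exp(-p$lambda01 * (f - p$mu01)),
              ifelse(f <= p$mu02,
                     p$lambda02 / 2 * exp(-p$lambda02 * (p$mu02 - f)),
                     max(p$lambda01, p$lambda02) / 2))
  d <- d / z
  if (log) base::log(d) else d
}

# ---- inference --------------------------------------------------------

#' Posterior over cadence classes for one analysis window
#'
#' Bayes' rule over \{null, cadence grid\}: per class, the likelihood is
#' the product of the per-feature densities (Gaussian for cadence classes,
#' [null_density()] for the null class) times the class prior, normalised
#' to sum to 1.  Computed in log space; if every class underflows to zero
#' likelihood the prior is returned unchanged.
#'
#' @param f a [step_features()] object, or a list/vector with `f1`, `f2`.
#' @param m a [speed_model_set()].
#' @return Named posterior vector over `c("null", <cadences>)`, sums to 1.
#' @export
speed_posterior <- function(f, m) {
  stopifnot(inherits(m, "speed_model_set"))
  f1 <- as.numeric(f[["f1"]]); f2 <- as.numeric(f[["f2"]])
  ll <- c(null = null_density(f1, m$null$f1, log = TRUE) +
            null_density(f2, m$null$f2, log = TRUE),
          vapply(m$speeds, function(s)
            dnorm(f1, s$f1$lambda, s$f1$sigma, log = TRUE) +
              dnorm(f2, s$f2$lambda, s$f2$sigma, log = TRUE), 0))
  lp <- ll + log(m$prior)
  if (all(!is.finite(lp))) return(m$prior)
  lp <- lp - max(lp[is.finite(lp)])
  w <- exp(lp)
  w[!is.finite(w)] <- 0
  w / sum(w)
}

#' Probability that a window contains a step
#'
#' The posterior mass on the cadence classes, i.e. `1 - posterior["null"]`.
#'
#' @param posterior a [speed_posterior()] result (sums to 1, first entry
#'   named `null`).
#' @return A single probability in \[0, 1\].
#' @export
step_probability <- function(posterior) {
  if (abs(sum(posterior) - 1) > 1e-6) stopf("posterior must sum to 1")
  unname(1 - posterior[["null"]])
}

#' Fall-detection score and decision
#'
#' The score is the product of peak-normalised Gaussian kernels
#' `exp(-(x - lambda)^2 / (2 sigma^2))` over the two fall features; a fall
#' is declared when the score exceeds `tau2` (default 0.1).  Equivalently,
#' the decision boundary at tau2 = 0.1 is joint squared standardised
#' distance `2 ln 10`.
#'
#' @param f a [fall_features()] object, or a list/vector with `f1` (g) and
#'   `f2` (ms).
#' @param m a [fall_model()].
#' @return List `(score, is_fall)`; `score` is in (0, 1].
#' @export
fall_likelihood <- function(f, m) {
  stopifnot(inherits(m, "fall_model"))
  k <- function(x, p) exp(-(x - p$lambda)^2 / (2 * p$sigma^2))
  score <- k(as.numeric(f[["f1"]]), m$f1) * k(as.numeric(f[["f2"]]), m$f2)
  list(score = score, is_fall = score > m$tau2)
}

#' Classify a detected fall
#'
#' Per class, the score is the product of peak-normalised Gaussian kernels
#' over the three impact-axis features; the highest-scoring class wins,
#' with ties broken in class order c1, c2, c3.  If per-class thresholds
#' `tau` are set in the model, classes scoring below threshold are
#' excluded and `c3` ("other fall") is the fallback when none qualifies.
#'
#' @param f a [fall_class_features()] object, or a list/vector with `f1`,
#'   `f2`, `f3` (Gx, Gy, Gz at the impact peak, g).
#' @param m a [fall_class_model()].
#' @return List `(class, label, scores)`.
#' @export
classify_fall <- function(f, m) {
  stopifnot(inherits(m, "fall_class_model"))
  x <- c(as.numeric(f[["f1"]]), as.numeric(f[["f2"]]), as.numeric(f[["f3"]]))
  scores <- vapply(m$classes, function(cl) {
    prod(vapply(seq_len(3), function(j) {
      p <- cl[[j]]
      exp(-(x[j] - p$lambda)^2 / (2 * p$sigma^2))
    }, 0))
  }, 0)
  if (!is.null(m$tau)) {
    ok <- scores > m$tau
    cls <- if (any(ok)) names(scores)[ok][which.max(scores[ok])] else "c3"
  } else {
    cls <- names(scores)[which.max(scores)]
  }
  list(class = cls, label = unname(m$labels[cls]), scores = scores)
}
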