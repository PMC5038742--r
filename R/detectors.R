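#' Sliding-window detector configuration
#'
#' @param delta_max step analysis window length in seconds (default 0.9 s).
#'   The window must cover the longest single-step extrema pattern
#'   (about 0.5 s at 60 steps/min) yet stay short enough that some window
#'   position isolates one step from its neighbours even at 100 steps/min
#'   (stride period 0.6 s); windows much longer than one period pair the
#'   maximum of one step with the minimum of the next and corrupt the
#'   timing feature.
#' @param hop window stride in seconds (default 0.1; must be <= delta_max).
#' @param theta step decision threshold on p(step | f1, f2) (default 0.5).
#' @param refractory minimum gap between step events in seconds
#'   (default 0.3).
#' @param fall_window fall analysis window length in seconds (default 2.5,
#'   long enough to hold the free-fall dip and the impact spike).
#' @param fall_refractory minimum gap between fall events in seconds
#'   (default 2.0).
#' @return A `detector_config` list.
#' @export
detector_config <- function(delta_max = 0.9, hop = 0.1, theta = 0.5,
                            refractory = 0.3, fall_window = 2.5,
                            fall_refractory = 2.0) {
  if (hop > delta_max) stopf("detector_config: hop must be <= delta_max")
  if (refractory <= 0 || fall_refractory <= 0) stopf("detector_config: refractory must be > 0")
  if (delta_max <= 0 || hop <= 0 || fall_window <= 0) stopf("detector_config: window lengths must be > 0")
  structure(list(delta_max = delta_max, hop = hop, theta = theta,
                 refractory = refractory, fall_window = fall_window,
                 fall_refractory = fall_refractory),
            class = "detector_config")
}

empty_events <- function() {
  data.frame(kind = character(), time_s = numeric(), score = numeric(),
             label = character(), inserted = logical(), stringsAsFactors = FALSE)
}

# Greedy refractory merge: cluster time-sorted candidates whose anchor
# times are within `refractory` of the previous cluster member, keep the
# highest-scoring candidate per cluster (earliest on ties).
merge_candidates <- function(cand, refractory) {
  if (nrow(cand) == 0L) return(cand)
  cand <- cand[order(cand$time_s), , drop = FALSE]
  cluster <- cumsum(c(1, diff(cand$time_s) > refractory))
  keep <- unlist(lapply(split(seq_len(nrow(cand)), cluster), function(ix)
    ix[which.max(cand$score[ix])]), use.names = FALSE)
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect steps in a recording
#'
#' Slides a `delta_max` window over the oriented recording with stride
#' `hop`; per window, extracts [step_features()], evaluates
#' [speed_posterior()] and [step_probability()], and keeps windows with
#' probability above `theta` as candidates anchored at the time of the
#' vertical-acceleration maximum in the window (a heel-strike proxy).
#' Candidates within the refractory period of each other are merged,
#' keeping the highest probability.
#'
#' @param oriented a [project_components()] result.
#' @param m a [speed_model_set()].
#' @param cfg a [detector_config()].
#' @return Event data.frame with columns `kind` (`"step"`), `time_s`,
#'   `score` (step probability), `label` (maximum-posterior cadence),
#'   `inserted` (`FALSE`).  Shorter-than-window recordings return an empty
#'   frame with a warning.
#' @export
detect_steps <- function(oriented, m = default_speed_model(), cfg = detector_config()) {
  stopifnot(inherits(oriented, "oriented_series"), inherits(m, "speed_model_set"),
            inherits(cfg, "detector_config"))
  n <- length(oriented$vertical)
  extent <- (n - 1) / oriented$fs
  if (extent < cfg$delta_max) {
    warning("recording shorter than the analysis window; no step detection performed")
    return(empty_events())
  }
  starts <- seq(oriented$t0, oriented$t0 + extent - cfg$delta_max, by = cfg$hop)
  rows <- lapply(starts, function(s0) {
    f <- step_features(oriented, s0, cfg$delta_max)
    post <- speed_posterior(f, m)
    p <- step_probability(post)
    if (p <= cfg$theta) return(NULL)
    wv <- window_extrema(oriented$vertical, s0, cfg$delta_max, oriented$fs, oriented$t0)
    speeds <- post[setdiff(names(post), "null")]
    data.frame(kind = "step", time_s = wv$max$time, score = p,
               label = names(speeds)[which.max(speeds)], inserted = FALSE,
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, rows)
  if (is.null(cand)) return(empty_events())
  merge_candidates(cand, cfg$refractory)
}

#' Insert steps missed inside an otherwise periodic run
#'
#' Steps are periodic, so a single missed detection shows up as a gap of
#' roughly twice the surrounding inter-step interval.  Within each run of
#' events (runs are split where a gap exceeds 3x the median interval), any
#' gap within `tolerance` (relative) of twice the median of the run's
#' other intervals gets one event inserted at its midpoint, flagged
#' `inserted`.  Original events are never altered or removed.
#'
#' @param events time-sorted event data.frame (as from [detect_steps()]).
#' @param tolerance relative tolerance on the "twice the interval" rule
#'   (default 0.2).
#' @return The event frame with any inserted events added (time-sorted).
#'   Fewer than 3 events are returned unchanged.
#' @export
correct_periodic <- function(events, tolerance = 0.2) {
  if (nrow(events) < 3L) return(events)
  if (is.unsorted(events$time_s)) stopf("correct_periodic: events must be time-sorted")
  t <- events$time_s
  iv <- diff(t)
  med <- median(iv)
  run_id <- cumsum(c(1, as.numeric(iv > 3 * med)))
  inserted <- list()
  for (r in unique(run_id)) {
    ix <- which(run_id == r)           # event indices of this run
    if (length(ix) < 3L) next
    riv <- diff(t[ix])
    for (j in seq_along(riv)) {
      m <- median(riv[-j])
      if (!is.finite(m) || m <= 0) next
      if (abs(riv[j] - 2 * m) <= tolerance * 2 * m) {
        a <- ix[j]; b <- ix[j + 1]
        inserted[[length(inserted) + 1L]] <- data.frame(
          kind = events$kind[a], time_s = (t[a] + t[b]) / 2,
          score = mean(c(events$score[a], events$score[b])),
          label = events$label[a], inserted = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(inserted) == 0L) return(events)
  out <- rbind(events, do.call(rbind, inserted))
  out <- out[order(out$time_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect and classify falls in a recording
#'
#' Slides a `fall_window` window with stride `hop`; per window, extracts
#' [fall_features()] on the acceleration magnitude and scores them with
#' [fall_likelihood()].  Supra-threshold windows are anchored at the |G|
#' maximum (the impact) and merged within the fall refractory period; each
#' merged event is classified from the raw axis values at the impact peak
#' via [classify_fall()].
#'
#' @param series the raw [accel_series()].
#' @param oriented the matching [project_components()] result.
#' @param fm a [fall_model()].
#' @param fcm a [fall_class_model()].
#' @param cfg a [detector_config()].
#' @return Event data.frame with columns `kind` (`"fall"`), `time_s`
#'   (impact time), `score`, `label` (class c1/c2/c3), `inserted`
#'   (`FALSE`).
#' @export
detect_falls <- function(series, oriented, fm = default_fall_model(),
                         fcm = default_fall_class_model(), cfg = detector_config()) {
  stopifnot(inherits(series, "accel_series"), inherits(oriented, "oriented_series"),
            inherits(fm, "fall_model"), inherits(fcm, "fall_class_model"),
            inherits(cfg, "detector_config"))
  n <- length(oriented$magnitude)
  extent <- (n - 1) / oriented$fs
  if (extent < cfg$fall_window) {
    warning("recording shorter than the fall window; no fall detection performed")
    return(empty_events())
  }
  starts <- seq(oriented$t0, oriented$t0 + extent - cfg$fall_window, by = cfg$hop)
  rows <- lapply(starts, function(s0) {
    f <- fall_features(oriented, s0, cfg$fall_window)
    lk <- fall_likelihood(f, fm)
    if (!lk$is_fall) return(NULL)
    w <- window_extrema(oriented$magnitude, s0, cfg$fall_window, oriented$fs, oriented$t0)
    data.frame(kind = "fall", time_s = w$max$time, score = lk$score,
               start = s0, stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, rows)
  if (is.null(cand)) return(empty_events())
  merged <- merge_candidates(cand, cfg$fall_refractory)
  merged$label <- vapply(seq_len(nrow(merged)), function(i) {
    fc <- fall_class_features(series, oriented, merged$start[i], cfg$fall_window)
    classify_fall(fc, fcm)$class
  }, "")
  merged$inserted <- FALSE
  merged$start <- NULL
  merged[, c("kind", "time_s", "score", "label", "inserted")]
}
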