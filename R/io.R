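MODEL_SCHEMA <- "stepfall-model-v1"
G_PER_MS2 <- 9.80665

#' Read an accelerometer time series from CSV
#'
#' Expects the header `t,ax,ay,az`: time in seconds, axes in the declared
#' units.  Input in m/s^2 is converted to g (1 g = 9.80665 m/s^2).
#' Non-uniform timestamps are linearly interpolated onto a uniform grid at
#' `fs_override` (or at the median input rate if not given).
#'
#' @param path CSV file path.
#' @param units `"g"` or `"ms2"` (m/s^2).
#' @param fs_override optional sampling rate (Hz) to resample onto.
#' @return An [accel_series()].
#' @export
read_series <- function(path, units = c("g", "ms2"), fs_override = NULL) {
  units <- match.arg(units)
  if (!file.exists(path)) stopf("input file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "ax", "ay", "az")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  df <- df[need]
  for (nm in need) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stopf("%s: non-finite or non-numeric value in column '%s' at line %d",
            path, nm, bad[1] + 1L)   # +1 for the header line
    df[[nm]] <- v
  }
  if (nrow(df) < 1L) stopf("%s: no data rows", path)
  dt <- diff(df$t)
  bad <- which(dt <= 0)
  if (length(bad))
    stopf("%s: time column not strictly increasing at line %d", path, bad[1] + 2L)
  xyz <- as.matrix(df[c("ax", "ay", "az")])
  if (units == "ms2") xyz <- xyz / G_PER_MS2
  if (nrow(df) == 1L) {
    fs <- fs_override %||% stopf("%s: single-sample file needs fs_override", path)
    return(accel_series(xyz, fs = fs, t0 = df$t[1]))
  }
  med <- median(dt)
  uniform <- max(abs(dt - med)) <= 0.01 * med
  if (uniform && is.null(fs_override)) {
    return(accel_series(xyz, fs = 1 / med, t0 = df$t[1]))
  }
  fs <- fs_override %||% (1 / med)
  tt <- seq(df$t[1], df$t[nrow(df)], by = 1 / fs)
  out <- vapply(1:3, function(j) approx(df$t, xyz[, j], xout = tt)$y,
                numeric(length(tt)))
  accel_series(out, fs = fs, t0 = df$t[1])
}

#' Write an accelerometer series to CSV
#'
#' Writes the standard `t,ax,ay,az` format in g units.
#'
#' @param series an [accel_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "accel_series"))
  df <- data.frame(t = series_times(series), series$xyz)
  write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read detection events
#'
#' Event CSV columns: `kind,time_s,score,label,inserted`.
#'
#' @param events event data.frame (as from [detect_steps()]).
#' @param path file path.
#' @return `path` (write) or the event data.frame (read).
#' @export
write_events <- function(events, path) {
  write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stopf("events file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(kind = "character", time_s = "numeric",
                                score = "numeric", label = "character",
                                inserted = "logical"))
  df
}

#' Write / read ground-truth sidecars
#'
#' Ground-truth CSV columns: `kind,time_s,label`.
#'
#' @param truth data.frame with columns `kind`, `time_s`, `label`.
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_ground_truth <- function(truth, path) {
  write.csv(truth[c("kind", "time_s", "label")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stopf("ground-truth file not found: %s", path)
  read.csv(path, stringsAsFactors = FALSE)
}

# ---- model bundle -----------------------------------------------------

#' Bundle all movement models into one deployable object
#'
#' A single artifact holds the step (cadence) model set, the fall
#' detection and classification models, and the torso-location
#' calibration, mirroring a single-sensor deployment.
#'
#' @param step a [speed_model_set()].
#' @param fall a [fall_model()].
#' @param fall_class a [fall_class_model()].
#' @param calibration a [location_calibration()].
#' @return A `movement_model` list.
#' @export
movement_model <- function(step = default_speed_model(),
                           fall = default_fall_model(),
                           fall_class = default_fall_class_model(),
                           calibration = default_location_calibration()) {
  stopifnot(inherits(step, "speed_model_set"), inherits(fall, "fall_model"),
            inherits(fall_class, "fall_class_model"),
            inherits(calibration, "location_calibration"))
  structure(list(step = step, fall = fall, fall_class = fall_class,
                 calibration = calibration),
            class = "movement_model")
}

#' Save / load a movement model as JSON
#'
#' The file carries a schema tag plus unit metadata (step f1 in g, step f2
#' in s, fall f2 in ms) and round-trips all parameters exactly.
#'
#' @param model a [movement_model()].
#' @param path JSON file path.
#' @return `path` (save) or the reconstructed [movement_model()] (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "movement_model"))
  step <- model$step
  doc <- list(
    schema = MODEL_SCHEMA,
    units = list(step_f1 = "g", step_f2 = "s", fall_f1 = "g", fall_f2 = "ms",
                 fall_class = "g"),
    step = list(
      delta_max = step$delta_max,
      prior = as.list(step$prior),
      speeds = lapply(step$speeds, function(s)
        list(mu = s$mu_label,
             f1 = c(s$f1$lambda, s$f1$sigma), f2 = c(s$f2$lambda, s$f2$sigma))),
      null = lapply(step$null, function(p)
        list(lambda01 = p$lambda01, mu01 = p$mu01,
             lambda02 = p$lambda02, mu02 = p$mu02))),
    fall = list(f1 = c(model$fall$f1$lambda, model$fall$f1$sigma),
                f2 = c(model$fall$f2$lambda, model$fall$f2$sigma),
                tau2 = model$fall$tau2),
    fall_class = list(
      classes = lapply(model$fall_class$classes, function(cl)
        lapply(cl, function(p) c(p$lambda, p$sigma))),
      tau = if (is.null(model$fall_class$tau)) NULL else as.list(model$fall_class$tau)),
    calibration = list(lower_torso = as.list(model$calibration$lower_torso),
                       upper_torso = as.list(model$calibration$upper_torso)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, MODEL_SCHEMA))
    stopf("model schema mismatch: expected '%s', found '%s'",
          MODEL_SCHEMA, doc$schema %||% "<none>")
  speeds <- lapply(doc$step$speeds, function(s)
    speed_gaussian(s$mu, f1 = as.numeric(s$f1), f2 = as.numeric(s$f2)))
  null <- lapply(doc$step$null, function(p)
    null_feature(p$lambda01, p$mu01, p$lambda02, p$mu02))
  prior <- unlist(doc$step$prior)
  step <- speed_model_set(speeds, null, prior = prior,
                          delta_max = doc$step$delta_max)
  fall <- fall_model(as.numeric(doc$fall$f1), as.numeric(doc$fall$f2),
                     tau2 = doc$fall$tau2)
  fc_tau <- if (is.null(doc$fall_class$tau) || length(doc$fall_class$tau) == 0) NULL
            else unlist(doc$fall_class$tau)
  fall_class <- fall_class_model(
    lapply(doc$fall_class$classes, function(cl) lapply(cl, as.numeric)),
    tau = fc_tau)
  calibration <- location_calibration(unlist(doc$calibration$lower_torso),
                                      unlist(doc$calibration$upper_torso))
  movement_model(step = step, fall = fall, fall_class = fall_class,
                 calibration = calibration)
}
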