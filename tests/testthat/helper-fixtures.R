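# Shared fixtures and independent oracles, generated in code at test time.

rand_series <- function(n = 500, fs = 50, seed = 1, sd = 0.3) {
  set.seed(seed)
  accel_series(matrix(rnorm(3 * n, 0, sd), ncol = 3) +
                 matrix(rep(c(0, 0, 1), each = n), ncol = 3),
               fs = fs)
}

# brute-force centred sliding mean over +/- window_s/2 seconds
brute_sliding_mean <- function(xyz, fs, window_s) {
  n <- nrow(xyz)
  out <- xyz * 0
  for (k in seq_len(n)) {
    tk <- (k - 1) / fs
    sel <- abs((seq_len(n) - 1) / fs - tk) <= window_s / 2 + 1e-12
    out[k, ] <- colMeans(xyz[sel, , drop = FALSE])
  }
  out
}

# explicit-product Bayes arithmetic, independent of speed_posterior()
brute_bayes <- function(f1, f2, m) {
  lik <- c(null_density(f1, m$null$f1) * null_density(f2, m$null$f2),
           vapply(m$speeds, function(s)
             dnorm(f1, s$f1$lambda, s$f1$sigma) * dnorm(f2, s$f2$lambda, s$f2$sigma), 0))
  names(lik)[1] <- "null"
  w <- lik * m$prior
  w / sum(w)
}

# a random but valid model set for property tests
rand_model_set <- function(seed) {
  set.seed(seed)
  speeds <- lapply(c(60, 80, 100), function(mu)
    speed_gaussian(mu, f1 = c(runif(1, 0.2, 1), runif(1, 0.05, 0.5)),
                   f2 = c(runif(1, 0.02, 0.3), runif(1, 0.01, 0.1))))
  null <- list(f1 = null_feature(runif(1, 5, 50), runif(1, 0.05, 0.2),
                                 runif(1, 5, 50), runif(1, -0.2, 0.04)),
               f2 = null_feature(runif(1, 2, 20), runif(1, 0.1, 0.5),
                                 runif(1, 2, 20), runif(1, -0.5, 0)))
  p <- runif(4); p <- p / sum(p)
  names(p) <- c("null", "60", "80", "100")
  speed_model_set(speeds, null, prior = p)
}

# project a synthetic series against its true constant gravity (0, 0, 1)
project_known_gravity <- function(series) {
  flat <- accel_series(matrix(rep(c(0, 0, 1), each = nrow(series$xyz)), ncol = 3),
                       fs = series$fs, t0 = series$t0)
  project_components(series, estimate_gravity(flat))
}

oriented_from <- function(series) project_components(series, estimate_gravity(series))
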