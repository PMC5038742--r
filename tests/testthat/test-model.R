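test_that("fit_gaussian: closed forms and degenerate input", {
  expect_equal(fit_gaussian(c(1, 1, 1)), c(lambda = 1, sigma = 1e-6))
  expect_equal(fit_gaussian(c(0, 2)), c(lambda = 1, sigma = sqrt(2)))
  expect_error(fit_gaussian(1), "at least 2")
})

test_that("fit_gaussian recovers the tabulated 60 steps/min f1 parameters", {
  x <- draw_features(0.4846, 0.2023, 1e4, seed = 101)
  fit <- fit_gaussian(x)
  expect_lt(abs(fit["lambda"] - 0.4846), 4 * 0.2023 / sqrt(1e4))
  expect_lt(abs(fit["sigma"] - 0.2023), 4 * 0.2023 / sqrt(2e4))
})

test_that("fit_null: symmetry, tail-rate recovery, unit mass", {
  set.seed(31)
  sym <- c(rnorm(5000), -rnorm(5000))
  p <- fit_null(sym)
  expect_equal(p$mu01, -p$mu02, tolerance = 0.05)
  expect_equal(p$lambda01, p$lambda02, tolerance = 0.1 * p$lambda01)

  # synthetic sample with known exponential tails beyond +/- 1
  set.seed(32)
  n <- 1e4
  smp <- c(runif(n / 2, -1, 1), 1 + rexp(n / 4, 2), -1 - rexp(n / 4, 3))
  p2 <- fit_null(smp)
  expect_equal(p2$mu01, 1, tolerance = 0.05)
  expect_equal(p2$mu02, -1, tolerance = 0.05)
  expect_lt(abs(p2$lambda01 - 2) / 2, 0.10)
  expect_lt(abs(p2$lambda02 - 3) / 3, 0.10)

  for (p in list(p, p2, null_feature(4, 0.3, 9, -0.1))) {
    mass <- stats::integrate(function(x) null_density(x, p), -50, 50,
                             subdivisions = 2000)$value
    expect_equal(mass, 1, tolerance = 1e-4)
  }
  expect_error(fit_null(c(1, 2)), "at least 4")
})

test_that("speed_posterior: degenerate and symmetric cases", {
  m1 <- speed_model_set(list(speed_gaussian(80, c(0.7, 0.3), c(0.12, 0.07))),
                        default_null_model(),
                        prior = c(null = 0, `80` = 1))
  expect_equal(unname(speed_posterior(list(f1 = 0.7, f2 = 0.12), m1)), c(0, 1))

  same <- list(speed_gaussian(60, c(0.5, 0.2), c(0.1, 0.05)),
               speed_gaussian(100, c(0.5, 0.2), c(0.1, 0.05)))
  m2 <- speed_model_set(same, default_null_model(),
                        prior = c(null = 0, `60` = 0.5, `100` = 0.5))
  post <- speed_posterior(list(f1 = 0.43, f2 = 0.08), m2)
  expect_equal(post[["60"]], post[["100"]])
})

test_that("speed_posterior at the tabulated 100 steps/min features", {
  m <- default_speed_model()
  post <- speed_posterior(list(f1 = 0.8141, f2 = 0.0688), m)
  expect_equal(names(which.max(post)), "100")
  expect_equal(unname(post), unname(brute_bayes(0.8141, 0.0688, m)), tolerance = 1e-12)
})

test_that("speed_posterior equals brute-force Bayes on random models", {
  set.seed(44)
  for (rep in 1:100) {
    m <- rand_model_set(seed = rep)
    f1 <- runif(1, -0.2, 1.5)
    f2 <- runif(1, -0.5, 0.5)
    post <- speed_posterior(list(f1 = f1, f2 = f2), m)
    expect_equal(sum(post), 1, tolerance = 1e-12)
    expect_true(all(post >= 0 & post <= 1))
    expect_equal(unname(post), unname(brute_bayes(f1, f2, m)), tolerance = 1e-12)
  }
})

test_that("speed_posterior falls back to the prior when no class has mass", {
  m <- default_speed_model()
  post <- speed_posterior(list(f1 = Inf, f2 = 0.1), m)
  expect_equal(post, m$prior)
  # extreme-but-finite features still normalise via log space
  post2 <- speed_posterior(list(f1 = 1e6, f2 = 1e6), m)
  expect_equal(sum(post2), 1, tolerance = 1e-12)
})

test_that("step_probability is 1 minus the null mass", {
  expect_equal(step_probability(c(null = 0.2, `60` = 0.5, `80` = 0.3)), 0.8)
  expect_equal(step_probability(c(null = 1, `60` = 0, `80` = 0)), 0)
  set.seed(9)
  for (rep in 1:20) {
    p <- runif(4); p <- p / sum(p); names(p) <- c("null", "60", "80", "100")
    expect_equal(step_probability(p), 1 - p[["null"]])
  }
})

test_that("step_probability decreases as the null likelihood rises", {
  m0 <- default_speed_model()
  # f1 inside the null plateau: raising the dominant tail rate strictly
  # raises the plateau density (lambda / (2 + width * lambda)), all else fixed
  f <- list(f1 = 0.06, f2 = 0.1)
  probs <- vapply(c(1, 10, 100, 1000), function(scale) {
    m <- m0
    m$null$f1$lambda01 <- m0$null$f1$lambda01 * scale
    step_probability(speed_posterior(f, m))
  }, 0)
  expect_true(all(diff(probs) < 0))
})

test_that("fall_likelihood: peak, decision boundary, far tail", {
  m <- default_fall_model()
  at_peak <- fall_likelihood(list(f1 = m$f1$lambda, f2 = m$f2$lambda), m)
  expect_equal(at_peak$score, 1.0)
  expect_true(at_peak$is_fall)

  # tau2 = 0.1 boundary == joint squared standardised distance 2 ln 10
  grid <- expand.grid(z1 = seq(-3, 3, 0.2), z2 = seq(-3, 3, 0.2))
  sc <- mapply(function(z1, z2)
    fall_likelihood(list(f1 = m$f1$lambda + z1 * m$f1$sigma,
                         f2 = m$f2$lambda + z2 * m$f2$sigma), m)$score,
    grid$z1, grid$z2)
  expect_identical(sc > 0.1, grid$z1^2 + grid$z2^2 < 2 * log(10))
  expect_true(all(sc > 0 & sc <= 1))

  far <- fall_likelihood(list(f1 = m$f1$lambda + 10 * m$f1$sigma,
                              f2 = m$f2$lambda + 10 * m$f2$sigma), m)
  expect_lt(far$score, 1e-20)
  expect_false(far$is_fall)
})

test_that("classify_fall: peak score, tie rule, thresholds", {
  m <- default_fall_class_model()
  r <- classify_fall(list(f1 = 5.2423, f2 = 1.9998, f3 = -1.8940), m)
  expect_equal(r$class, "c1")
  expect_equal(unname(r$scores["c1"]), 1.0)

  # equidistant in standardised units from two equal-sigma classes -> c1 wins
  msym <- fall_class_model(list(
    c1 = list(f1 = c(0, 1), f2 = c(0, 1), f3 = c(0, 1)),
    c2 = list(f1 = c(2, 1), f2 = c(0, 1), f3 = c(0, 1)),
    c3 = list(f1 = c(10, 1), f2 = c(10, 1), f3 = c(10, 1))))
  expect_equal(classify_fall(list(f1 = 1, f2 = 0, f3 = 0), msym)$class, "c1")

  # thresholds: all classes excluded -> fallback c3
  mt <- fall_class_model(stepfall:::fall_class_table(),
                         tau = c(c1 = 0.99, c2 = 0.99, c3 = 0.99))
  r2 <- classify_fall(list(f1 = 6, f2 = 0, f3 = -3), mt)
  expect_equal(r2$class, "c3")
})

test_that("well-separated class draws are always classified correctly", {
  m <- default_fall_class_model()
  tab <- stepfall:::fall_class_table()
  set.seed(77)
  for (cl in c("c1", "c2", "c3")) {
    for (i in 1:100) {
      x <- vapply(tab[[cl]], function(p) {
        repeat {
          v <- rnorm(1, p[1], p[2])
          if (abs(v - p[1]) <= 0.5 * p[2]) return(v)
        }
      }, 0)
      expect_equal(classify_fall(list(f1 = x[1], f2 = x[2], f3 = x[3]), m)$class, cl)
    }
  }
})

test_that("parameter recovery holds for every tabulated pair at n = 1000", {
  tabs <- c(
    lapply(seq_len(3), function(i) stepfall:::step_table()$f1[i, ]),
    lapply(seq_len(3), function(i) stepfall:::step_table()$f2[i, ]),
    stepfall:::fall_table(),
    unlist(stepfall:::fall_class_table(), recursive = FALSE))
  n <- 1e3
  for (k in seq_along(tabs)) {
    lam <- tabs[[k]][1]; sig <- tabs[[k]][2]
    fit <- fit_gaussian(draw_features(lam, sig, n, seed = 500 + k))
    expect_lt(abs(fit["lambda"] - lam), 4 * sig / sqrt(n))
    expect_lt(abs(fit["sigma"] - sig), 4 * sig / sqrt(2 * n))
  }
})
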