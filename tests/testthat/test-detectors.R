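test_that("detect_steps: quiet input, threshold bound, short recording", {
  flat <- synth_null("sitting", duration = 20, fs = 50, seed = 2)
  o <- oriented_from(flat)
  expect_equal(nrow(detect_steps(o)), 0)

  w <- synth_walk(walk_spec(seed = 1))
  ow <- oriented_from(w$series)
  ev_all <- detect_steps(ow)
  expect_gt(nrow(ev_all), 0)
  ev_none <- detect_steps(ow, cfg = detector_config(theta = 1.0))
  expect_equal(nrow(ev_none), 0)

  short <- accel_series(cbind(0, 0, rep(1, 10)), fs = 50)
  expect_warning(ev <- detect_steps(oriented_from(short)), "shorter")
  expect_equal(nrow(ev), 0)
})

test_that("detect_steps finds the 20 steps of the default walk", {
  w <- synth_walk(walk_spec(cadence = 80, n_steps = 20, seed = 1))
  ev <- detect_steps(oriented_from(w$series))
  res <- eval_events(ev, data.frame(kind = "step", time_s = w$step_times,
                                    label = "80"), tol_s = 0.3)
  expect_equal(res$matched, 20)
  expect_equal(mean(diff(ev$time_s[!ev$inserted])), 0.75, tolerance = 0.05)
  expect_true(all(ev$score > 0.5 & ev$score <= 1))
})

test_that("detect_steps is shift-invariant under quiet padding", {
  w <- synth_walk(walk_spec(n_steps = 8, noise_sd = 0, seed = 4))
  ev <- detect_steps(oriented_from(w$series))
  pad_s <- 1.5
  n_pad <- pad_s * w$series$fs
  padded <- accel_series(rbind(matrix(rep(c(0, 0, 1), each = n_pad), ncol = 3),
                               w$series$xyz), fs = w$series$fs)
  ev_pad <- detect_steps(oriented_from(padded))
  expect_equal(nrow(ev_pad), nrow(ev))
  expect_equal(ev_pad$time_s, ev$time_s + pad_s, tolerance = 1e-9)
})

test_that("raising theta never increases step counts", {
  w <- synth_walk(walk_spec(seed = 6))
  o <- oriented_from(w$series)
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8, 0.95), function(th)
    nrow(detect_steps(o, cfg = detector_config(theta = th))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("correct_periodic repairs the constructed single miss", {
  e <- data.frame(kind = "step", time_s = c(1, 2, 4, 5, 6), score = 1,
                  label = "80", inserted = FALSE, stringsAsFactors = FALSE)
  out <- correct_periodic(e)
  expect_equal(out$time_s, 1:6)
  expect_equal(out$inserted, c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))

  reg <- data.frame(kind = "step", time_s = seq(0, 5, 0.75), score = 1,
                    label = "80", inserted = FALSE, stringsAsFactors = FALSE)
  expect_identical(correct_periodic(reg), reg)

  two <- reg[1:2, ]
  expect_identical(correct_periodic(two), two)
})

test_that("correct_periodic repairs simulated deletions without spurious inserts", {
  set.seed(15)
  repaired <- 0; deleted <- 0; spurious <- 0
  for (trial in 1:100) {
    n <- 20
    t <- cumsum(c(1, 0.75 * (1 + runif(n - 1, -0.03, 0.03))))
    ev <- data.frame(kind = "step", time_s = t, score = 0.9, label = "80",
                     inserted = FALSE, stringsAsFactors = FALSE)
    del <- which(runif(n) < 0.1)
    del <- del[del > 1 & del < n]
    if (length(del) > 1) del <- del[c(TRUE, diff(del) > 1)]  # single misses only
    if (!length(del)) next
    out <- correct_periodic(ev[-del, ])
    expect_true(all(ev$time_s[-del] %in% out$time_s))        # originals kept
    expect_gte(nrow(out), nrow(ev) - length(del))
    ins <- out$time_s[out$inserted]
    for (dt in ev$time_s[del])
      if (length(ins) && any(abs(ins - dt) < 0.2)) repaired <- repaired + 1
    deleted <- deleted + length(del)
    if (length(ins))
      spurious <- spurious + sum(vapply(ins, function(x)
        all(abs(ev$time_s[del] - x) >= 0.2), TRUE))
  }
  expect_gt(deleted, 50)
  expect_gte(repaired / deleted, 0.95)
  expect_equal(spurious, 0)
})

test_that("detect_falls: quiet input yields nothing, embedded fall is found", {
  quiet <- synth_null("sitting", duration = 10, fs = 100, seed = 3)
  oq <- oriented_from(quiet)
  expect_equal(nrow(detect_falls(quiet, oq)), 0)

  r <- synth_fall(fall_spec("c1", fs = 100, pre_s = 15, post_s = 12,
                            context = "walking", seed = 7))
  o <- oriented_from(r$series)
  ev <- detect_falls(r$series, o)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$label, "c1")
  expect_lt(abs(ev$time_s - r$fall_time), 0.5)
})

test_that("a 0.1x-amplitude impact scores below the detection threshold", {
  r <- synth_fall(fall_spec("c2", seed = 11))
  o <- oriented_from(r$series)
  # shrink the dynamic part of |G| about the 1 g baseline
  o$magnitude <- 1 + 0.1 * (o$magnitude - 1)
  f <- fall_features(o, r$fall_time - 1.2, 2.5)
  lk <- fall_likelihood(f, default_fall_model())
  expect_false(lk$is_fall)
  expect_lt(lk$score, 0.1)
})

test_that("raising tau2 never increases fall counts", {
  r <- synth_fall(fall_spec("c3", seed = 5))
  o <- oriented_from(r$series)
  tab <- stepfall:::fall_table()
  counts <- vapply(c(0.01, 0.1, 0.5, 0.9), function(tau)
    nrow(detect_falls(r$series, o, fall_model(tab$f1, tab$f2, tau2 = tau))), 0L)
  expect_true(all(diff(counts) <= 0))
})
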