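test_that("cycle detection recovers exact periodicity and polarity symmetry", {
  e <- synth_egg(f0 = 100, contact_quotient_pct = 40, duration_s = 2, seed = 1)
  fs <- attr(e, "sample_rate")
  cyc <- detect_cycles(e, fs)
  expect_true(all(abs(cyc$period - 0.010) <= 1 / fs))
  # inverted polarity with the invert flag gives identical instants
  cyc2 <- detect_cycles(-e, fs, voq_config(egg_invert = TRUE))
  expect_equal(cyc2$closure, cyc$closure, tolerance = 1e-9)
})

test_that("square-wave EGG yields the duty cycle as Qx", {
  fs <- 16000
  for (duty in c(0.4, 0.5)) {
    per <- fs / 100
    x <- rep(c(rep(1, round(per * duty)), rep(0, per - round(per * duty))), 150)
    cyc <- contact_quotient(x, detect_cycles(x, fs))
    expect_equal(mean(cyc$qx, na.rm = TRUE), 100 * duty, tolerance = 1)
  }
})

test_that("a programmed 60% contact quotient is recovered within 5 points", {
  e <- synth_egg(f0 = 100, contact_quotient_pct = 60, duration_s = 3, seed = 2)
  cyc <- contact_quotient(e, detect_cycles(e, attr(e, "sample_rate")))
  expect_lt(abs(mean(cyc$qx, na.rm = TRUE) - 60), 5)
})

test_that("CFx and CQx follow their closed forms", {
  mk <- function(fx, qx = NA) {
    cyc <- data.frame(closure = cumsum(c(0, 1 / fx[-length(fx)])),
                      period = 1 / fx, fx = fx, qx = qx)
    class(cyc) <- c("voq_cycles", "data.frame")
    cyc
  }
  expect_equal(cfx(mk(rep(100, 10))), 0)
  expect_equal(cfx(mk(rep(c(99, 101), 10))), 2.0, tolerance = 1e-9)
  # fx (100, 100, 110): mean|d| = 5, mean fx = 310/3
  expect_equal(cfx(mk(c(100, 100, 110))), 100 * 5 / (310 / 3),
               tolerance = 1e-12)
  cyc <- mk(rep(100, 3)); cyc$qx <- c(40, 42, 50)
  expect_equal(cqx(cyc), 5.0)
  cyc$qx <- rep(c(40, 44), length.out = 3)
  expect_equal(cqx(cyc), 4.0)
  cyc$qx <- rep(40, 3)
  expect_equal(cqx(cyc), 0)
  expect_error(cfx(mk(100)), class = "voq_undefined")
})

test_that("CFx/CQx are invariant under EGG amplitude scaling", {
  e <- synth_egg(f0 = 110, contact_quotient_pct = 50, cycle_perturb_pct = 2,
                 qx_perturb_pct = 2, duration_s = 2, seed = 3)
  fs <- attr(e, "sample_rate")
  s1 <- egg_summary(as.numeric(e), fs)
  s2 <- egg_summary(as.numeric(e) * 12.7, fs)
  expect_equal(s1$cfx, s2$cfx, tolerance = 1e-9)
  expect_equal(s1$cqx, s2$cqx, tolerance = 1e-9)
  expect_equal(s1$n_cycles, s2$n_cycles)
})

test_that("CFx grows strictly with the injected cycle perturbation", {
  est <- sapply(c(0, 1, 2, 5), function(cp) {
    e <- synth_egg(f0 = 100, contact_quotient_pct = 50,
                   cycle_perturb_pct = cp, duration_s = 3, seed = 4)
    egg_summary(as.numeric(e), attr(e, "sample_rate"))$cfx
  })
  expect_true(all(diff(est) > 0))
  expect_lt(est[1], 0.1)          # no perturbation -> CFx ~ 0
  expect_gte(est[3], 1.6)         # 2% in [1.6, 2.4]
  expect_lte(est[3], 2.4)
})

test_that("a ramped Fx contour is tracked within 3% per cycle", {
  e <- synth_egg(f0 = function(t) 120 + 30 * t, contact_quotient_pct = 50,
                 duration_s = 2, seed = 3)
  cyc <- detect_cycles(e, attr(e, "sample_rate"))
  tc <- attr(e, "true_cycles")
  near <- vapply(cyc$closure, function(t)
    tc$period[which.min(abs(tc$closure - t))], 1)
  expect_lt(max(abs(cyc$period - near) / near), 0.03)
})

test_that("edge silence changes CFx/CQx by less than 0.1", {
  e <- synth_egg(f0 = 100, contact_quotient_pct = 50, cycle_perturb_pct = 1,
                 duration_s = 2, seed = 5)
  fs <- attr(e, "sample_rate")
  s1 <- egg_summary(as.numeric(e), fs)
  padded <- c(numeric(fs %/% 10), as.numeric(e), numeric(fs %/% 10))
  s2 <- egg_summary(padded, fs)
  expect_lt(abs(s1$cfx - s2$cfx), 0.1)
  expect_lt(abs(s1$cqx - s2$cqx), 0.1)
})

test_that("degenerate EGG input raises an empty-series condition", {
  expect_error(detect_cycles(numeric(16000), 16000),
               class = "voq_empty_series")
  expect_error(detect_cycles(rnorm(100), 4000), class = "voq_config_error")
})
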