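test_that("a noiseless staircase is exact", {
  tr <- simulate_trace(108, 100, c(1, 2, 3), noise_sd = 0,
                       sampling_rate = 2000, duration = 5, seed = 1)
  expect_equal(sort(unique(tr$I)), c(0, 10.8, 21.6, 32.4), tolerance = 1e-12)
  ev <- detect_jumps(tr)
  expect_identical(nrow(ev), 3L)
  expect_equal(ev$delta_I, rep(10.8, 3), tolerance = 1e-9)
  expect_true(all(ev$sign == "insertion"))
})

test_that("simulation is deterministic given the seed", {
  t1 <- simulate_trace(108, 100, c(1), noise_sd = 2, duration = 3, seed = 9)
  t2 <- simulate_trace(108, 100, c(1), noise_sd = 2, duration = 3, seed = 9)
  expect_identical(t1$I, t2$I)
  t3 <- simulate_trace(108, 100, c(1), noise_sd = 2, duration = 3, seed = 10)
  expect_false(identical(t1$I, t3$I))
})

test_that("post-insertion level means follow the generative conductance", {
  tr <- simulate_trace(200, 100, c(1), noise_sd = 1.5,
                       sampling_rate = 5000, duration = 5, seed = 3)
  lvl <- mean(tr$I[tr$t > 1.1])
  n <- sum(tr$t > 1.1)
  expect_lt(abs(lvl - 20), 4 * 1.5 / sqrt(n))
})

test_that("detection on a noisy staircase recovers all events with accurate amplitudes", {
  ins <- c(0.8, 2.1, 3.4, 4.2)
  tr <- simulate_trace(108, 100, ins, noise_sd = 1,
                       sampling_rate = 5000, duration = 6, seed = 21)
  ev <- detect_jumps(tr)
  expect_identical(nrow(ev), length(ins))
  expect_true(all(abs(ev$time - ins) < 0.05))
  expect_true(all(abs(ev$delta_I - 10.8) / 10.8 < 0.05))
})

test_that("a flat trace yields no events and bad windows error", {
  tr <- simulate_trace(108, 100, numeric(0), noise_sd = 1,
                       sampling_rate = 2000, duration = 2, seed = 4)
  expect_identical(nrow(detect_jumps(tr)), 0L)
  expect_error(detect_jumps(tr, window = 5), "window")
})

test_that("degenerate and sampled histograms fit correctly", {
  ev <- data.frame(time = 1:6, delta_I = rep(10.8, 6),
                   pre_mean = 0, post_mean = 10.8, sign = "insertion")
  class(ev) <- c("jump_events", "data.frame")
  fit <- fit_single_channel(ev)
  expect_equal(fit$mu, 10.8, tolerance = 1e-9)
  expect_lt(fit$sd, 0.5)
  expect_identical(sum(fit$counts), fit$n_events)
  expect_error(fit_single_channel(ev[1:3, ]), "at least 5")

  set.seed(31)
  amps <- rnorm(40, 10.8, 1.5)
  ev2 <- data.frame(time = seq_along(amps), delta_I = amps,
                    pre_mean = 0, post_mean = amps, sign = "insertion")
  class(ev2) <- c("jump_events", "data.frame")
  fit2 <- fit_single_channel(ev2, bin_width = 0.5)
  expect_lt(abs(fit2$mu - 10.8), 2 * 1.5 / sqrt(40) + 0.5)
})

test_that("multi-insertion jumps are excluded from the single-channel cluster", {
  amps <- c(rnorm(20, 10.8, 0.5), rnorm(5, 21.6, 0.5))   # doubles
  set.seed(2)
  ev <- data.frame(time = seq_along(amps), delta_I = amps,
                   pre_mean = 0, post_mean = amps, sign = "insertion")
  class(ev) <- c("jump_events", "data.frame")
  fit <- fit_single_channel(ev)
  expect_lt(abs(fit$mu - 10.8), 1)
  expect_identical(fit$n_events, 20L)
})

test_that("conductance from the fit is unit-consistent and sign-invariant", {
  fit <- list(mu = 10.8, sd = 1, n_events = 25)
  expect_equal(conductance_from_fit(fit, 100)$G, 108)
  fit2 <- list(mu = 42.7, sd = 1, n_events = 25)
  expect_equal(conductance_from_fit(fit2, 100)$G, 427)
  fitm <- list(mu = -10.8, sd = 1, n_events = 25)
  expect_equal(conductance_from_fit(fitm, -100)$G, 108)
  expect_error(conductance_from_fit(fit, 0), "nonzero")
})

test_that("IV analysis flags ohmic behavior and reports rectification", {
  mk <- function(V, G) simulate_trace(G, V, numeric(0), noise_sd = 0.5,
                                      sampling_rate = 1000, duration = 1,
                                      seed = 5 + V) |>
    (\(tr) { tr$I <- tr$I + G * V * 1e-3; tr })()
  Vs <- c(-100, -50, 50, 100)
  trs <- lapply(Vs, mk, G = 108)
  iv <- iv_analysis(trs)
  expect_true(all(iv$monotone))
  expect_equal(iv$rectification, 1, tolerance = 0.05)
  # order invariance
  iv2 <- iv_analysis(trs[c(3, 1, 4, 2)])
  expect_equal(iv2$curve, iv$curve)
  # injected rectification stays monotone but shows asymmetry
  trs3 <- c(lapply(c(-100, -50), mk, G = 108), lapply(c(50, 100), mk, G = 160))
  iv3 <- iv_analysis(trs3)
  expect_true(all(iv3$monotone))
  expect_gt(iv3$rectification, 1.3)
  expect_error(iv_analysis(trs[1:2]), ">= 3")
})

test_that("the simulate-detect-fit pipeline recovers the generative conductance", {
  # noise at 15 % of the step amplitude, many seeds
  errs <- vapply(1:20, function(s) {
    ins <- c(0.6, 1.5, 2.4, 3.3, 4.2, 5.1)
    tr <- simulate_trace(108, 100, ins, noise_sd = 0.15 * 10.8,
                         sampling_rate = 5000, duration = 6, seed = s)
    ev <- detect_jumps(tr)
    fit <- fit_single_channel(ev)
    abs(conductance_from_fit(fit, 100)$G - 108) / 108
  }, numeric(1))
  expect_true(all(errs < 0.05))
})

test_that("the detector false-positive rate on pure noise is low", {
  events <- sum(vapply(1:10, function(s) {
    tr <- simulate_trace(0, 100, numeric(0), noise_sd = 2,
                         sampling_rate = 5000, duration = 10, seed = 100 + s)
    nrow(detect_jumps(tr))
  }, numeric(1)))
  # < 0.1 events per second over 100 s of noise
  expect_lt(events / 100, 0.1)
})
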