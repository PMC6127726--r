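test_that("the reference level pools frames before and after the event", {
  # flat trace outside a transient
  ev <- make_event(c(rep(1, 15), 1.2, 1.5, 1.2, rep(1, 15)),
                   onset = 16L, end = 18L)
  ev <- compute_reference(ev)
  expect_equal(ev$f_pre, 1.0)
  expect_equal(ev$amplitude_dF, 0.5)

  # elevated post-event baseline: pre 1.0, post 1.2 -> mean 1.1
  ev <- make_event(c(rep(1, 10), 1.6, 1.8, 1.6, rep(1.2, 10)),
                   onset = 11L, end = 13L)
  ev <- compute_reference(ev, n_ref_frames = 10L)
  expect_equal(ev$f_pre, 1.1)
  expect_false("one_sided_reference" %in% ev$flags)

  # event at the end of the window: one-sided mean, flagged
  ev <- make_event(c(rep(1, 10), 1.6, 1.8), onset = 11L, end = 12L)
  ev <- compute_reference(ev)
  expect_equal(ev$f_pre, 1.0)
  expect_true("one_sided_reference" %in% ev$flags)
})

test_that("kinetics match closed-form linear interpolation on triangular pulses", {
  dt_ms <- 5.32
  # rising linearly over 10 frames: 20->100% spans 8 frames
  ev <- compute_kinetics(compute_reference(triangle_event(up = 10L, down = 10L)))
  expect_equal(ev$rise_ms, 0.8 * 10 * dt_ms, tolerance = 1e-9)
  expect_equal(ev$decay_ms, 0.8 * 10 * dt_ms, tolerance = 1e-9)
  # symmetric triangle: FWHM = half the base
  expect_equal(ev$fwhm_ms, 10 * dt_ms, tolerance = 1e-9)
  expect_identical(ev$rise_ms, ev$decay_ms)

  # asymmetric triangle
  ev <- compute_kinetics(compute_reference(triangle_event(up = 5L, down = 20L)))
  expect_equal(ev$rise_ms, 0.8 * 5 * dt_ms, tolerance = 1e-9)
  expect_equal(ev$decay_ms, 0.8 * 20 * dt_ms, tolerance = 1e-9)
  expect_equal(ev$fwhm_ms, 0.5 * (5 + 20) * dt_ms, tolerance = 1e-9)

  # single-frame spike: rise and decay each bounded by one frame interval
  tr <- c(rep(1, 12), 1.8, rep(1, 12))
  ev <- compute_kinetics(compute_reference(make_event(tr, onset = 13L, end = 13L)))
  expect_lte(ev$rise_ms, dt_ms)
  expect_lte(ev$decay_ms, dt_ms)
})

test_that("kinetics are invariant to offset and joint rescaling, and censoring flags", {
  base <- triangle_event(up = 8L, down = 12L)
  k0 <- compute_kinetics(compute_reference(base))
  # additive offset
  shifted <- base; shifted$trace <- base$trace + 3
  shifted$f_peak <- max(shifted$trace)
  k1 <- compute_kinetics(compute_reference(shifted))
  expect_equal(k1$rise_ms, k0$rise_ms)
  expect_equal(k1$decay_ms, k0$decay_ms)
  expect_equal(k1$fwhm_ms, k0$fwhm_ms)
  # joint rescale of the whole trace
  scaled <- base; scaled$trace <- base$trace * 2.5
  scaled$f_peak <- max(scaled$trace)
  k2 <- compute_kinetics(compute_reference(scaled))
  expect_equal(k2$rise_ms, k0$rise_ms)
  expect_equal(k2$fwhm_ms, k0$fwhm_ms)

  # trace that never falls back below 20%: right-censored decay
  tr <- c(rep(1, 10), seq(1, 2, length.out = 6), rep(2, 10))
  ev <- make_event(tr, onset = 11L, end = 26L, peak = 16L)
  ev <- compute_kinetics(compute_reference(ev))
  expect_true("decay_censored" %in% ev$flags)

  # unimodal property: FWHM never exceeds rise + decay
  set.seed(31)
  for (i in 1:20) {
    up <- sample(3:15, 1); down <- sample(3:15, 1)
    inc <- sort(runif(up)); dec <- sort(runif(down), decreasing = TRUE)
    tr <- c(rep(0, 12), cumsum(inc) / sum(inc))
    tr <- c(tr, tr[length(tr)] * dec / max(dec), rep(0, 12)) + 1
    ev <- make_event(tr, onset = 13L, end = 12L + up + down)
    ev <- compute_kinetics(compute_reference(ev))
    expect_lte(ev$fwhm_ms, ev$rise_ms + ev$decay_ms + 1e-9)
  }
})

test_that("staircase segmentation recovers unitary steps", {
  # noise-free 3-step staircase, >= 3 frames per plateau
  tr <- c(rep(1.303, 4), rep(1.202, 4), rep(1.101, 4), rep(1.000, 8))
  st <- estimate_unitary_step(trace = tr)
  expect_equal(st$n_steps, 3L)
  expect_equal(st$unitary_dF, 0.101, tolerance = 1e-12)
  expect_true(all(diff(st$step_levels) < 0))

  # smooth monotone decay: the fitted plateaus track the curve, so the
  # drops are many and far smaller than a quantal step
  st <- estimate_unitary_step(trace = 1 + 0.3 * exp(-(0:29) / 8))
  expect_lt(st$unitary_dF, 0.05)

  # too-short decay segment is a precondition failure
  expect_error(estimate_unitary_step(trace = c(1.2, 1.1, 1.0)), ">= 4")

  # noisy staircases: per-puff medians scatter around the true step and
  # their mean converges on it
  set.seed(17)
  est <- numeric(10)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    lens <- sample(4:8, k + 1, replace = TRUE)
    levels <- 1 + 0.101 * (k:0)
    tr <- rep(levels, lens) + rnorm(sum(lens), 0, 0.01)
    st <- estimate_unitary_step(trace = tr)
    expect_gte(st$n_steps, 1L)
    expect_lt(abs(st$unitary_dF - 0.101), 0.02)
    est[i] <- st$unitary_dF
  }
  expect_lt(abs(mean(est) - 0.101), 0.005)
})

test_that("channel counting divides the amplitude by the unitary step", {
  ev <- make_event(c(rep(1, 12), 1.101, rep(1, 12)), onset = 13L, end = 13L)
  ev <- count_channels(compute_reference(ev))
  expect_equal(ev$n_channels, 1.0, tolerance = 1e-9)
  expect_equal(ev$n_channels_round, 1L)

  ev <- make_event(c(rep(1, 12), 1.303, rep(1, 12)), onset = 13L, end = 13L)
  ev <- count_channels(compute_reference(ev))
  expect_equal(ev$n_channels, 3.0, tolerance = 1e-9)
  expect_equal(ev$n_channels_round, 3L)

  # zero amplitude reports 0 with a flag
  ev <- make_event(rep(1, 25), onset = 13L, end = 13L)
  ev <- count_channels(compute_reference(ev))
  expect_equal(ev$n_channels, 0)
  expect_equal(ev$n_channels_round, 0L)
  expect_true("zero_amplitude" %in% ev$flags)

  expect_error(count_channels(ev, unitary_dF = 0), "positive")
})

test_that("pooling unitary steps gives mean, s.e.m. and count", {
  mk <- function(v) structure(list(step_levels = c(1 + v, 1),
                                   plateau_lengths = c(3, 3), unitary_dF = v,
                                   n_steps = 1L, flags = character(0)),
                              class = "step_estimate")
  p <- pool_unitary_step(rep(list(mk(0.1)), 40))
  expect_equal(p$unitary_dF, 0.1)
  expect_equal(p$sem, 0)
  expect_equal(p$n, 40)

  p <- pool_unitary_step(list(mk(0.09), mk(0.11)))
  expect_equal(p$unitary_dF, 0.10)
  expect_equal(p$sem, 0.01, tolerance = 1e-12)

  expect_error(pool_unitary_step(list()), "no step estimates")
})
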