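test_that("baseline statistics are the per-pixel mean and population s.d.", {
  mv <- ca_movie(array(100, c(4, 4, 20)), 0.005, 0.16, 11L)
  bl <- compute_baseline(mv, 10L)
  expect_true(all(bl$f0_map == 100))
  expect_true(all(bl$sd_map == 0))

  # alternating 99/101 over an even count: f0 = 100, population s.d. = 1
  f <- array(rep(c(99, 101), each = 16), c(4, 4, 21))
  mv <- ca_movie(f, 0.005, 0.16, 21L)
  bl <- compute_baseline(mv, 20L)
  expect_true(all(abs(bl$f0_map - 100) < 1e-12))
  expect_true(all(abs(bl$sd_map - 1) < 1e-12))

  expect_error(compute_baseline(ca_movie(array(1, c(2, 2, 5)), 0.005, 0.16, 1L)),
               "no pre-flash")
  expect_warning(compute_baseline(ca_movie(array(1, c(2, 2, 5)), 0.005, 0.16, 3L)),
                 "available")
})

test_that("baseline estimates match their sampling distributions", {
  set.seed(99)
  n <- 500L
  f <- array(rnorm(20 * 20 * (n + 2), 100, 5), c(20, 20, n + 2))
  mv <- ca_movie(f, 0.00532, 0.16, n + 1L)
  bl <- compute_baseline(mv, n)
  # se(mean) = 5/sqrt(500) = 0.224; se(sd) ~ 5/sqrt(2*500) = 0.16
  expect_gte(mean(abs(bl$f0_map - 100) < 1), 0.99)
  expect_gte(mean(abs(bl$sd_map - 5) < 0.7), 0.99)
})

test_that("normalization applies [(F/F0)-1]/sd with the s.d. in F/F0 units", {
  # F = f0 everywhere -> z = 0
  mv <- ca_movie(array(100, c(3, 3, 4)), 0.005, 0.16, 3L)
  f0 <- matrix(100, 3, 3); sdm <- matrix(2, 3, 3)
  ns <- normalize_stack(mv, f0, sdm, gaussian_sigma_px = 0)
  expect_true(all(ns$z == 0))

  # f0 = 100, sd = 2 camera units (0.02 in F/F0 units)
  f <- array(100, c(3, 3, 4)); f[2, 2, 3] <- 105
  mv <- ca_movie(f, 0.005, 0.16, 3L)
  ns <- normalize_stack(mv, f0, sdm, gaussian_sigma_px = 0)
  expect_equal(ns$z[2, 2, 3], 0.05 / 0.02, tolerance = 1e-12)
  f[2, 2, 3] <- 110
  ns <- normalize_stack(ca_movie(f, 0.005, 0.16, 3L), f0, sdm, 0)
  expect_equal(ns$z[2, 2, 3], 0.10 / 0.02, tolerance = 1e-12)

  # sigma = 0 equals the arithmetic oracle exactly on random input
  set.seed(4)
  f <- array(rexp(5 * 4 * 6, 1 / 100), c(5, 4, 6))
  f0r <- matrix(runif(20, 80, 120), 5, 4)
  sdr <- matrix(runif(20, 1, 4), 5, 4)
  ns <- normalize_stack(ca_movie(f, 0.005, 0.16, 2L), f0r, sdr, 0)
  oracle <- array(0, dim(f))
  for (t in 1:6) oracle[, , t] <- ((f[, , t] / f0r) - 1) / pmax(sdr / f0r, 1e-3)
  expect_identical(ns$z, oracle)

  # dead pixels are masked and reported
  f0r[1, 1] <- 0
  expect_message(
    ns <- normalize_stack(ca_movie(f, 0.005, 0.16, 2L), f0r, sdr, 0),
    "masked 1")
  expect_true(all(ns$z[1, 1, ] == 0))
  expect_equal(ns$n_masked, 1L)
})

test_that("pre-flash z is centred on zero for noise-only input", {
  set.seed(21)
  f <- array(rnorm(20 * 20 * 300, 500, 10), c(20, 20, 300))
  mv <- ca_movie(f, 0.00532, 0.16, 251L)
  bl <- compute_baseline(mv, 250L)
  ns <- normalize_stack(mv, bl$f0_map, bl$sd_map)
  pre_mean <- rowMeans(matrix(ns$z[, , 1:250], nrow = 400))
  expect_gte(mean(abs(pre_mean) < 0.1), 0.99)
})

test_that("a rendered 3-channel puff at default noise clears the 0.8 threshold", {
  cfg <- sim_config(n_sites = 1L, duration_s = 3, flash_time_s = 1.4, seed = 8)
  sites <- data.frame(site_id = 1L, x_um = 9.6, y_um = 9.6)
  set.seed(8)
  truth <- make_ground_truth(cfg, sites, onsets = 1.8, site_ids = 1L,
                             n_channels = 3L)
  mv <- render_movie(cfg, truth)
  bl <- compute_baseline(mv, 260L)
  ns <- normalize_stack(mv, bl$f0_map, bl$sd_map)
  cy <- round(9.6 / 0.16 + 0.5)
  expect_gte(max(ns$z[(cy - 2):(cy + 2), (cy - 2):(cy + 2), ]), 0.8)
})

test_that("threshold-clustering finds isolated events and separates sites and times", {
  # constant (noise-free) stack -> no events
  mv <- ca_movie(array(100, c(10, 10, 50)), 0.00532, 0.16, 11L)
  bl <- compute_baseline(mv, 10L)
  ns <- normalize_stack(mv, bl$f0_map, bl$sd_map)
  expect_length(detect_events(ns, mv), 0)

  # one noise-free puff -> one event at the right place and time
  cfg <- sim_config(n_sites = 1L, duration_s = 3, flash_time_s = 1,
                    noise = list(model = "none"), seed = 1)
  sites <- data.frame(site_id = 1L, x_um = 9.57, y_um = 9.63)
  set.seed(2)
  truth <- make_ground_truth(cfg, sites, onsets = 1.5, site_ids = 1L,
                             n_channels = 3L)
  mv <- render_movie(cfg, truth)
  bl <- compute_baseline(mv, 180L)
  ns <- normalize_stack(mv, bl$f0_map, bl$sd_map)
  ev <- detect_events(ns, mv)
  expect_length(ev, 1)
  expect_lt(abs(ev[[1]]$centroid_x_um - 9.57), 0.16)
  expect_lt(abs(ev[[1]]$centroid_y_um - 9.63), 0.16)
  open_frames <- c(ceiling(1.5 / cfg$dt_s) + 1L,
                   floor(max(truth$closures[[1]]) / cfg$dt_s) + 1L)
  expect_lte(ev[[1]]$window[["start"]], open_frames[1])
  expect_gte(ev[[1]]$window[["end"]], open_frames[2])

  # two sites 3 um apart, overlapping in time -> two events
  sites2 <- data.frame(site_id = 1:2, x_um = c(8, 11), y_um = c(9.6, 9.6))
  set.seed(3)
  truth2 <- make_ground_truth(cfg, sites2, onsets = c(1.5, 1.51),
                              site_ids = 1:2, n_channels = c(3L, 3L))
  mv2 <- render_movie(cfg, truth2)
  ns2 <- normalize_stack(mv2, bl$f0_map, bl$sd_map)
  ev2 <- detect_events(ns2, mv2)
  expect_length(ev2, 2)
  cx <- sort(vapply(ev2, function(e) e$centroid_x_um, numeric(1)))
  expect_equal(cx, c(8, 11), tolerance = 0.2)

  # same site, two puffs separated by sub-threshold frames -> two events
  set.seed(4)
  truth3 <- make_ground_truth(cfg, sites, onsets = c(1.3, 2.2),
                              site_ids = c(1L, 1L), n_channels = c(3L, 3L))
  mv3 <- render_movie(cfg, truth3)
  ns3 <- normalize_stack(mv3, bl$f0_map, bl$sd_map)
  expect_length(detect_events(ns3, mv3), 2)
})

test_that("event count is monotone non-increasing in the critical value", {
  sim <- simulate_movie(small_config(field_px = c(60L, 60L), duration_s = 4,
                                     n_sites = 4L))
  bl <- compute_baseline(sim$movie, 150L)
  ns <- normalize_stack(sim$movie, bl$f0_map, bl$sd_map)
  counts <- vapply(c(0.4, 0.8, 1.6), function(cv)
    length(detect_events(ns, sim$movie, critical_value = cv)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("2-D Gaussian fitting recovers sub-pixel centres and flags flat ROIs", {
  pixel <- 0.16
  mk_nstack <- function(img, Tn = 3L) {
    z <- array(0, c(nrow(img), ncol(img), Tn))
    z[, , 2] <- img
    structure(list(z = z, f0_map = matrix(1, nrow(img), ncol(img)),
                   sd_map = matrix(0, nrow(img), ncol(img)),
                   mask = matrix(FALSE, nrow(img), ncol(img)),
                   n_masked = 0L, dt_s = 0.00532, pixel_um = pixel,
                   flash_frame = 1L, gaussian_sigma_px = 0, sd_floor = 1e-3),
              class = "normalized_stack")
  }
  mk_ev <- function(py, px) {
    e <- make_event(trace = c(1, 2, 1), onset = 2L, end = 2L, peak = 2L)
    e$peak_px <- c(y = py, x = px); e$zpeak_frame <- 2L
    e$centroid_x_um <- (px - 0.5) * pixel
    e$centroid_y_um <- (py - 0.5) * pixel
    e
  }
  gauss_img <- function(cy_um, cx_um, n = 21L, sigma = 0.15) {
    cc <- (seq_len(n) - 0.5) * pixel
    5 * exp(-outer((cc - cy_um)^2, (cc - cx_um)^2, `+`) / (2 * sigma^2))
  }

  # centred exactly on a pixel centre: recovered to 1e-6 um
  ctr <- (11 - 0.5) * pixel
  ev <- fit_centroid(mk_ev(11L, 11L), mk_nstack(gauss_img(ctr, ctr)))
  expect_equal(ev$centroid_x_um, ctr, tolerance = 1e-6)
  expect_equal(ev$centroid_y_um, ctr, tolerance = 1e-6)

  # sub-pixel offset (+0.3, -0.2 px): recovered within 0.05 px
  ev <- fit_centroid(mk_ev(11L, 11L),
                     mk_nstack(gauss_img(ctr - 0.2 * pixel, ctr + 0.3 * pixel)))
  expect_lt(abs(ev$centroid_x_um - (ctr + 0.3 * pixel)) / pixel, 0.05)
  expect_lt(abs(ev$centroid_y_um - (ctr - 0.2 * pixel)) / pixel, 0.05)

  # flat ROI: fit flagged, brightest-pixel centre retained
  ev <- fit_centroid(mk_ev(11L, 11L), mk_nstack(matrix(1, 21, 21)))
  expect_true("centroid_fit_failed" %in% ev$flags)
  expect_equal(ev$centroid_x_um, ctr)
})

test_that("global-rise detection finds the onset and tolerates its absence", {
  cfg <- sim_config(n_sites = 0L, field_px = c(40L, 40L), duration_s = 16,
                    flash_time_s = 1,
                    global_rise = list(onset_s = 12, wave_speed_um_s = 30,
                                       plateau_dF = 1.0),
                    seed = 5)
  sim <- simulate_movie(cfg)
  bl <- compute_baseline(sim$movie, 150L)
  ns <- normalize_stack(sim$movie, bl$f0_map, bl$sd_map)
  g <- detect_global_rise(ns)
  expect_false(is.null(g))
  expect_lt(abs((g - 1) * cfg$dt_s - 12), 0.5)

  cfg0 <- sim_config(n_sites = 0L, field_px = c(40L, 40L), duration_s = 4,
                     flash_time_s = 1, seed = 5)
  sim0 <- simulate_movie(cfg0)
  bl0 <- compute_baseline(sim0$movie, 150L)
  ns0 <- normalize_stack(sim0$movie, bl0$f0_map, bl0$sd_map)
  expect_null(detect_global_rise(ns0))

  # an all-zero stack has no global rise
  mvz <- ca_movie(array(0, c(10, 10, 300)), 0.00532, 0.16, 150L)
  nsz <- structure(list(z = array(0, c(10, 10, 300)),
                        f0_map = matrix(1, 10, 10), sd_map = matrix(0, 10, 10),
                        mask = matrix(FALSE, 10, 10), n_masked = 0L,
                        dt_s = 0.00532, pixel_um = 0.16, flash_frame = 150L,
                        gaussian_sigma_px = 0, sd_floor = 1e-3),
                   class = "normalized_stack")
  expect_null(detect_global_rise(nsz))
})
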