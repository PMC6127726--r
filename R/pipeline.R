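#' Analysis parameters
#'
#' All tunables of the detection and quantification chain with their
#' defaults: the 0.8 critical value, the spatial Gaussian filter width, the
#' minimum event footprint/extent, the 100-frame window padding, the
#' 1.76 um measurement ROI, the 0.96 um site-separation rule, the 0.101
#' unitary step, the 10-frame reference and 500-frame baseline, and the
#' discovery-curve bin width.
#'
#' @param critical_value Detection threshold on the normalized stack.
#' @param gaussian_sigma_px Spatial filter s.d. in pixels.
#' @param sd_floor Floor on the baseline s.d. in F/F0 units.
#' @param min_px Minimum single-frame footprint of an event (pixels).
#' @param min_frames Minimum temporal extent of an event (frames).
#' @param pad_frames Window padding either side of an event (frames).
#' @param roi_um Side of the square measurement ROI (um).
#' @param sep_um Site-separation criterion (um).
#' @param unitary_dF Unitary fluorescence step used for channel counting.
#' @param n_ref_frames Reference frames each side of an event.
#' @param n_baseline_frames Pre-flash frames for the baseline statistics.
#' @param bin_s Discovery-curve bin width (s).
#' @param global_area_fraction,global_z_level,global_min_duration_s
#'   Parameters of [detect_global_rise()].
#' @param fit_centroids Refine centroids by 2-D Gaussian fitting.
#' @param estimate_steps Run the staircase step estimator per event.
#' @return A validated list of class `analysis_params`.
#' @export
analysis_params <- function(critical_value = 0.8, gaussian_sigma_px = 1.0,
                            sd_floor = 1e-3, min_px = 2L, min_frames = 2L,
                            pad_frames = 100L, roi_um = 1.76, sep_um = 0.96,
                            unitary_dF = 0.101, n_ref_frames = 10L,
                            n_baseline_frames = 500L, bin_s = 10,
                            global_area_fraction = 0.5, global_z_level = 0.8,
                            global_min_duration_s = 0.5,
                            fit_centroids = TRUE, estimate_steps = TRUE) {
  p <- list(critical_value = critical_value,
            gaussian_sigma_px = gaussian_sigma_px, sd_floor = sd_floor,
            min_px = as.integer(min_px), min_frames = as.integer(min_frames),
            pad_frames = as.integer(pad_frames), roi_um = roi_um,
            sep_um = sep_um, unitary_dF = unitary_dF,
            n_ref_frames = as.integer(n_ref_frames),
            n_baseline_frames = as.integer(n_baseline_frames), bin_s = bin_s,
            global_area_fraction = global_area_fraction,
            global_z_level = global_z_level,
            global_min_duration_s = global_min_duration_s,
            fit_centroids = isTRUE(fit_centroids),
            estimate_steps = isTRUE(estimate_steps))
  if (p$unitary_dF <= 0) stop("unitary_dF must be > 0")
  if (p$roi_um <= 0 || p$sep_um <= 0 || p$bin_s <= 0)
    stop("roi_um, sep_um and bin_s must be > 0")
  structure(p, class = "analysis_params")
}

#' Run the full puff analysis on a movie
#'
#' Chains the stages in their standard order: background subtraction (when a
#' background ROI is present), baseline statistics, normalization and
#' filtering, global-rise detection, event detection, centroid refinement,
#' per-puff reference/kinetics/step/channel-count metrics, site assignment,
#' discovery-curve fitting and the per-cell summary. Events starting at or
#' after a detected global rise are excluded and the effective recording is
#' truncated there.
#'
#' @param movie A [ca_movie()].
#' @param params An [analysis_params()].
#' @return A `puff_analysis` list: `events`, `sites`, `summary`,
#'   `discovery` (possibly `NULL`), `global_onset_frame`, `params` and
#'   `n_masked_pixels`.
#' @export
analyze_movie <- function(movie, params = analysis_params()) {
  stopifnot(inherits(movie, "ca_movie"), inherits(params, "analysis_params"))
  if (!is.null(movie$background_roi)) movie <- subtract_background(movie)
  bl <- compute_baseline(movie, params$n_baseline_frames)
  ns <- normalize_stack(movie, bl$f0_map, bl$sd_map,
                        gaussian_sigma_px = params$gaussian_sigma_px,
                        sd_floor = params$sd_floor)
  g <- detect_global_rise(ns, area_fraction = params$global_area_fraction,
                          z_level = params$global_z_level,
                          min_duration_s = params$global_min_duration_s)
  events <- detect_events(ns, movie, critical_value = params$critical_value,
                          min_px = params$min_px,
                          min_frames = params$min_frames,
                          pad_frames = params$pad_frames,
                          roi_um = params$roi_um)
  if (!is.null(g))
    events <- Filter(function(e) e$onset_frame < g, events)
  for (i in seq_along(events)) {
    e <- events[[i]]
    if (params$fit_centroids) e <- fit_centroid(e, ns)
    e <- compute_reference(e, params$n_ref_frames)
    e <- compute_kinetics(e)
    e <- count_channels(e, params$unitary_dF)
    if (params$estimate_steps) {
      st <- tryCatch(estimate_unitary_step(e), error = function(err) NULL)
      if (!is.null(st)) {
        e$unitary_dF_local <- st$unitary_dF
        e$n_steps <- st$n_steps
      }
    }
    events[[i]] <- e
  }
  asn <- assign_sites(events, sep_um = params$sep_um)
  summary <- summarize_cell(asn$events, asn$sites, movie,
                            global_onset_frame = g)
  discovery <- NULL
  eff <- summary$effective_recording_s
  if (nrow(asn$sites) > 0 && eff / params$bin_s >= 3) {
    discovery <- discovery_curve(asn$sites, bin_s = params$bin_s,
                                 window_s = c(0, eff))
    discovery <- tryCatch(fit_discovery_halftime(discovery),
                          error = function(err) discovery)
    if (is.finite(discovery$t_half_s)) {
      cv <- coverage_fraction(discovery$t_half_s, eff)
      discovery$n_half_lives <- cv$n_half_lives
      discovery$coverage_fraction <- cv$coverage_percent / 100
    }
  }
  structure(list(events = asn$events, sites = asn$sites, summary = summary,
                 discovery = discovery, global_onset_frame = g,
                 params = params, n_masked_pixels = ns$n_masked),
            class = "puff_analysis")
}

#' @export
print.puff_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("puff_analysis: %d puffs at %d sites; latency %.2f s, ",
           "frequency %.2f Hz over %.1f s%s\n"),
    s$total_puffs, s$total_sites, s$latency_first_puff_s,
    s$puff_frequency_hz, s$effective_recording_s,
    if (s$global_rise) sprintf(" (global rise at %.2f s)", s$global_onset_s)
    else ""))
  if (!is.null(x$discovery) && is.finite(x$discovery$t_half_s))
    cat(sprintf("  site discovery t1/2 = %.2f s; expected coverage %.1f%%\n",
                x$discovery$t_half_s, 100 * x$discovery$coverage_fraction))
  invisible(x)
}

#' Match detected events against simulator ground truth
#'
#' Greedy one-to-one matching: each ground-truth puff is matched to the
#' unmatched detected event whose ROI position lies within `max_dist_um` of
#' the puff's site and whose supra-threshold extent overlaps the puff's open
#' interval (onset to last closure, padded by `pad_s`).
#'
#' @param truth A `ground_truth`.
#' @param events List of detected `puff_event` objects.
#' @param max_dist_um Spatial matching tolerance.
#' @param pad_s Temporal matching tolerance.
#' @return A data.frame, one row per ground-truth puff: `puff_id`,
#'   `site_id`, `n_true`, `matched`, `event_id`, `dist_um`,
#'   `n_detected_round`. The fraction of detected events that match no puff
#'   is returned as the `false_discovery_rate` attribute.
#' @export
match_events <- function(truth, events, max_dist_um = 1.0, pad_s = 0.05) {
  stopifnot(inherits(truth, "ground_truth"))
  np <- nrow(truth$puffs)
  out <- data.frame(puff_id = truth$puffs$puff_id,
                    site_id = truth$puffs$site_id,
                    n_true = truth$puffs$n_channels,
                    matched = rep(FALSE, np),
                    event_id = rep(NA_integer_, np),
                    dist_um = rep(NA_real_, np),
                    n_detected_round = rep(NA_integer_, np))
  used <- logical(length(events))
  if (np && length(events)) {
    ex <- vapply(events, function(e) e$centroid_x_um, numeric(1))
    ey <- vapply(events, function(e) e$centroid_y_um, numeric(1))
    es <- vapply(events, function(e)
      (e$onset_frame - 1) * e$dt_s, numeric(1))
    ee <- vapply(events, function(e)
      (e$end_frame - 1) * e$dt_s, numeric(1))
    for (i in seq_len(np)) {
      si <- match(truth$puffs$site_id[i], truth$sites$site_id)
      dd <- sqrt((ex - truth$sites$x_um[si])^2 + (ey - truth$sites$y_um[si])^2)
      t0 <- truth$puffs$onset_s[i] - pad_s
      t1 <- max(truth$closures[[i]]) + pad_s
      cand <- which(!used & dd <= max_dist_um & es <= t1 & ee >= t0)
      if (length(cand)) {
        j <- cand[which.min(dd[cand])]
        used[j] <- TRUE
        out$matched[i] <- TRUE
        out$event_id[i] <- events[[j]]$event_id
        out$dist_um[i] <- dd[j]
        out$n_detected_round[i] <- events[[j]]$n_channels_round
      }
    }
  }
  attr(out, "false_discovery_rate") <-
    if (length(events)) mean(!used) else NA_real_
  out
}

#' Simulate-and-analyze recovery benchmark
#'
#' Runs `n_replicates` simulations (seeds `config$seed + 0:(n-1)`), analyses
#' each movie and scores recovery against the ground truth: detection recall
#' and precision, localization error, site-count error and the channel-count
#' confusion rate.
#'
#' @param config A [sim_config()].
#' @param params An [analysis_params()].
#' @param n_replicates Number of simulated movies.
#' @param max_dist_um Matching tolerance passed to [match_events()].
#' @return A data.frame with one row per replicate: `seed`, `n_true_puffs`,
#'   `n_detected`, `recall`, `precision`, `median_loc_err_px`,
#'   `n_true_sites`, `n_sites_detected`, `channel_count_accuracy`,
#'   `t_half_s`.
#' @export
run_benchmark <- function(config, params = analysis_params(),
                          n_replicates = 5L, max_dist_um = 1.0) {
  stopifnot(inherits(config, "sim_config"))
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    sim <- simulate_movie(cfg)
    res <- analyze_movie(sim$movie, params)
    m <- match_events(sim$truth, res$events, max_dist_um = max_dist_um)
    loc <- m$dist_um[m$matched] / cfg$pixel_um
    acc <- if (any(m$matched))
      mean(m$n_detected_round[m$matched] == m$n_true[m$matched]) else NA_real_
    rows[[r]] <- data.frame(
      seed = cfg$seed,
      n_true_puffs = nrow(sim$truth$puffs),
      n_detected = length(res$events),
      recall = if (nrow(m)) mean(m$matched) else NA_real_,
      precision = 1 - attr(m, "false_discovery_rate"),
      median_loc_err_px = if (length(loc)) median(loc) else NA_real_,
      n_true_sites = nrow(sim$truth$sites),
      n_sites_detected = nrow(res$sites),
      channel_count_accuracy = acc,
      t_half_s = if (!is.null(res$discovery)) res$discovery$t_half_s
                 else NA_real_)
  }
  do.call(rbind, rows)
}
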