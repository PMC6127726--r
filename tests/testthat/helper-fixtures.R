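# Fixtures are built in code; nothing is stored on disk.

# Minimal hand-built puff_event for metric-level tests. The trace covers
# frames window_start .. window_start + length(trace) - 1; onset/end mark the
# supra-threshold extent in absolute frame indices.
make_event <- function(trace, onset, end, peak = NULL, dt_s = 0.00532,
                       window_start = 1L, flash_frame = 1L, pixel_um = 0.16,
                       centroid = c(0, 0)) {
  rel <- (onset:end) - window_start + 1L
  peak <- peak %||% (window_start - 1L + rel[which.max(trace[rel])])
  structure(list(
    event_id = 1L, centroid_x_um = centroid[1], centroid_y_um = centroid[2],
    peak_px = c(y = 1L, x = 1L), zpeak_frame = as.integer(peak),
    z_peak = NA_real_, t_peak_frame = as.integer(peak),
    onset_frame = as.integer(onset), end_frame = as.integer(end),
    window = c(start = as.integer(window_start),
               end = as.integer(window_start + length(trace) - 1L)),
    trace = trace, f_peak = max(trace[rel]),
    f_pre = NA_real_, amplitude_dF = NA_real_,
    rise_ms = NA_real_, decay_ms = NA_real_, fwhm_ms = NA_real_,
    n_channels = NA_real_, n_channels_round = NA_integer_,
    unitary_dF_local = NA_real_, n_steps = NA_integer_,
    site_id = NA_integer_, dt_s = dt_s, pixel_um = pixel_um,
    flash_frame = as.integer(flash_frame), flags = character(0)),
    class = "puff_event")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Event with only the fields site assignment needs; `order` sets the peak
# frame so chronological processing follows the given sequence.
centroid_event <- function(x_um, y_um, order = 1L, dt_s = 0.00532,
                           flash_frame = 1L) {
  e <- make_event(trace = c(1, 2, 1), onset = 1L, end = 3L, peak = 2L,
                  dt_s = dt_s, flash_frame = flash_frame,
                  centroid = c(x_um, y_um))
  e$t_peak_frame <- as.integer(order)
  e$onset_frame <- as.integer(order)
  e
}

# Independent single-linkage clustering oracle: number of clusters when
# links longer than `sep` are cut.
single_linkage_count <- function(xy, sep) {
  if (nrow(xy) < 2L) return(nrow(xy))
  hc <- stats::hclust(stats::dist(xy), method = "single")
  max(stats::cutree(hc, h = sep))
}

# Triangular pulse: linear rise over `up` frames from base to base + amp,
# then linear fall over `down` frames, padded with `pad` baseline frames.
triangle_trace <- function(up = 10L, down = 10L, amp = 0.5, base = 1,
                           pad = 15L) {
  # the falling side uses (down - k)/down so that a symmetric pulse is a
  # bitwise mirror of its rising side
  c(rep(base, pad), base + amp * seq_len(up) / up,
    base + amp * (down - seq_len(down)) / down, rep(base, pad))
}

triangle_event <- function(up = 10L, down = 10L, amp = 0.5, base = 1,
                           pad = 15L, dt_s = 0.00532) {
  tr <- triangle_trace(up, down, amp, base, pad)
  make_event(tr, onset = pad + 1L, end = pad + up + down, peak = pad + up,
             dt_s = dt_s)
}

# Ground truth in which at most one puff is active at any time: puffs are
# scheduled round-robin across sites at a fixed global spacing. Channel
# counts are drawn from the config's distribution.
isolated_truth <- function(config, sites, rounds, gap_s = 0.11,
                           start_s = NULL) {
  n_puffs <- rounds * nrow(sites)
  onsets <- (start_s %||% (config$flash_time_s + 0.25)) +
    (seq_len(n_puffs) - 1L) * gap_s
  site_ids <- rep(sites$site_id, rounds)
  n_ch <- sample.int(config$channel_kmax, n_puffs, replace = TRUE,
                     prob = config$channel_pmf)
  make_ground_truth(config, sites, onsets, site_ids, n_ch)
}

# Small fast simulation config used across tests.
small_config <- function(...) {
  defaults <- list(n_sites = 10L, duration_s = 6, flash_time_s = 1.0,
                   site_min_sep_um = 2, puff_rate_hz = 0.4,
                   latency_scale_s = 0.2, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

small_params <- function(...) {
  analysis_params(n_baseline_frames = 150L, ...)
}
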