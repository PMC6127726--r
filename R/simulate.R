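#' Configuration for the synthetic TIRF movie generator
#'
#' Defaults emulate the recordings the analysis was designed for: 120 x 120
#' pixel frames at 160 nm/pixel, 188 Hz (5.32 ms/frame), a 42.7 s recording
#' with a photolysis flash after 2.7 s of baseline, puffs arising at fixed
#' clustered release sites with quantal amplitude structure (unitary
#' \eqn{\Delta F/F_0} step 0.101 per open channel, mostly fewer than seven
#' channels per puff) and an optional late global Ca2+ rise.
#'
#' The per-channel quantal amplitude is calibrated in the same units the
#' analysis measures: each open channel adds an isotropic 2-D Gaussian
#' (`psf_sigma_um`) scaled so that its mean over the 11 x 11 pixel
#' measurement ROI centred on the site equals `unitary_step_dF * baseline_f0`.
#'
#' @param n_sites Number of release sites.
#' @param field_px Frame size `c(Y, X)` in pixels.
#' @param pixel_um Pixel edge in micrometres.
#' @param dt_s Frame interval in seconds.
#' @param duration_s Total recording length in seconds.
#' @param flash_time_s Time of the photolysis flash (must be `< duration_s`).
#' @param site_min_sep_um Minimum pairwise distance between sites (um).
#' @param edge_margin_um Minimum distance of a site from the field edge (um),
#'   so the measurement ROI of every site lies inside the field.
#' @param puff_rate_hz Post-flash puff rate per site (Hz); a scalar, or a
#'   vector of length `n_sites` for rate heterogeneity across sites.
#' @param latency_scale_s Mean of the exponential latency between the flash
#'   and the start of each site's puff-generating Poisson process.
#' @param channel_mean Mean of the truncated-Poisson distribution of open
#'   channels per puff (ignored when `channel_pmf` is given).
#' @param channel_kmax Upper truncation of the channel count distribution.
#' @param channel_pmf Optional explicit probability vector over
#'   `1:channel_kmax`, overriding the truncated Poisson.
#' @param unitary_step_dF ROI-averaged \eqn{\Delta F/F_0} contributed by one
#'   open channel.
#' @param rise_ms Linear rise time of a puff (channels' summed signal ramps
#'   from 0 to full amplitude over this time).
#' @param open_dwell_ms Mean per-channel open dwell after the peak; channels
#'   close independently after exponential dwells, producing a descending
#'   staircase.
#' @param psf_sigma_um Standard deviation of the rendered Gaussian spot.
#' @param baseline_f0 Baseline fluorescence in camera units.
#' @param noise List: `list(model = "gaussian", sd_frac = 0.02)` for additive
#'   Gaussian noise with s.d. `sd_frac * baseline_f0`, or
#'   `list(model = "poisson", gain = g)` for shot noise (photon counts at
#'   `F/gain` scaled back by `gain`), or `list(model = "none")`.
#' @param global_rise Optional `list(onset_s, wave_speed_um_s, plateau_dF)`
#'   adding a circular plateau wave from a random pixel.
#' @param seed Integer seed; fixing it fixes the simulated movie bit-for-bit.
#'
#' @return A validated list of class `sim_config`. `channel_pmf` is filled in
#'   (Poisson with rate solved so the truncated mean equals `channel_mean`).
#' @export
sim_config <- function(n_sites = 30L,
                       field_px = c(120L, 120L),
                       pixel_um = 0.16,
                       dt_s = 0.00532,
                       duration_s = 42.7,
                       flash_time_s = 2.7,
                       site_min_sep_um = 0.96,
                       edge_margin_um = 1.0,
                       puff_rate_hz = 0.1,
                       latency_scale_s = 0.5,
                       channel_mean = 2.8,
                       channel_kmax = 10L,
                       channel_pmf = NULL,
                       unitary_step_dF = 0.101,
                       rise_ms = 25,
                       open_dwell_ms = 15,
                       psf_sigma_um = 0.15,
                       baseline_f0 = 500,
                       noise = list(model = "gaussian", sd_frac = 0.02),
                       global_rise = NULL,
                       seed = 1L) {
  cfg <- list(n_sites = as.integer(n_sites), field_px = as.integer(field_px),
              pixel_um = pixel_um, dt_s = dt_s, duration_s = duration_s,
              flash_time_s = flash_time_s, site_min_sep_um = site_min_sep_um,
              edge_margin_um = edge_margin_um, puff_rate_hz = puff_rate_hz,
              latency_scale_s = latency_scale_s, channel_mean = channel_mean,
              channel_kmax = as.integer(channel_kmax),
              channel_pmf = channel_pmf, unitary_step_dF = unitary_step_dF,
              rise_ms = rise_ms, open_dwell_ms = open_dwell_ms,
              psf_sigma_um = psf_sigma_um, baseline_f0 = baseline_f0,
              noise = noise, global_rise = global_rise,
              seed = as.integer(seed))
  if (cfg$n_sites < 0L) stop("n_sites must be >= 0")
  if (length(cfg$field_px) != 2L || any(cfg$field_px < 1L))
    stop("field_px must be c(Y, X) with positive entries")
  for (nm in c("pixel_um", "dt_s", "duration_s", "baseline_f0", "psf_sigma_um",
               "unitary_step_dF"))
    if (cfg[[nm]] <= 0) stop(nm, " must be > 0")
  for (nm in c("flash_time_s", "site_min_sep_um", "edge_margin_um",
               "latency_scale_s", "rise_ms", "open_dwell_ms"))
    if (any(cfg[[nm]] < 0)) stop(nm, " must be >= 0")
  if (any(cfg$puff_rate_hz < 0)) stop("puff_rate_hz must be >= 0")
  if (!length(cfg$puff_rate_hz) %in% c(1L, max(1L, cfg$n_sites)))
    stop("puff_rate_hz must be a scalar or one rate per site")
  if (cfg$flash_time_s >= cfg$duration_s)
    stop("flash_time_s must be < duration_s")
  if (cfg$channel_kmax < 1L) stop("channel_kmax must be >= 1")
  if (is.null(cfg$channel_pmf)) {
    cfg$channel_pmf <- truncated_poisson_pmf(cfg$channel_mean, cfg$channel_kmax)
  } else {
    if (length(cfg$channel_pmf) != cfg$channel_kmax || any(cfg$channel_pmf < 0) ||
        sum(cfg$channel_pmf) <= 0)
      stop("channel_pmf must be a non-negative vector over 1:channel_kmax")
    cfg$channel_pmf <- cfg$channel_pmf / sum(cfg$channel_pmf)
  }
  if (!is.list(cfg$noise) || is.null(cfg$noise$model) ||
      !cfg$noise$model %in% c("gaussian", "poisson", "none"))
    stop("noise$model must be one of 'gaussian', 'poisson', 'none'")
  if (!is.null(cfg$global_rise)) {
    gr <- cfg$global_rise
    if (!all(c("onset_s", "wave_speed_um_s", "plateau_dF") %in% names(gr)))
      stop("global_rise needs onset_s, wave_speed_um_s, plateau_dF")
  }
  structure(cfg, class = "sim_config")
}

#' Probability mass over 1..kmax of a Poisson truncated to that support,
#' with the rate solved so that the *truncated* mean equals `mean`.
#' @noRd
truncated_poisson_pmf <- function(mean, kmax) {
  k <- seq_len(kmax)
  if (kmax == 1L || mean <= 1) return(c(1, rep(0, kmax - 1L)))
  tmean <- function(lambda) {
    p <- dpois(k, lambda); p <- p / sum(p); sum(k * p)
  }
  if (mean >= kmax) stop("channel_mean must be < channel_kmax")
  lam <- uniroot(function(l) tmean(l) - mean, c(1e-8, 4 * kmax))$root
  p <- dpois(k, lam)
  p / sum(p)
}

#' Place release sites uniformly with a minimum separation
#'
#' Sites are fixed subcellular locations; rejection sampling draws uniform
#' positions within the field (inset by `edge_margin_um`) until all pairwise
#' distances are at least `site_min_sep_um`.
#'
#' Uses the current RNG state; call `set.seed()` first (or use
#' [simulate_movie()], which seeds from the config) for reproducibility.
#'
#' @param config A [sim_config()].
#' @param max_tries Rejection-sampling budget per site.
#' @return A data.frame with columns `site_id`, `x_um`, `y_um`.
#' @export
place_sites <- function(config, max_tries = 10000L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_sites
  Ly <- config$field_px[1] * config$pixel_um
  Lx <- config$field_px[2] * config$pixel_um
  m <- config$edge_margin_um
  if (n == 0L)
    return(data.frame(site_id = integer(0), x_um = numeric(0), y_um = numeric(0)))
  if (2 * m >= Lx || 2 * m >= Ly)
    stop("edge_margin_um leaves no room for sites in a ",
         round(Lx, 2), " x ", round(Ly, 2), " um field")
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      x <- runif(1, m, Lx - m); y <- runif(1, m, Ly - m)
      if (length(xs) == 0L ||
          min(sqrt((xs - x)^2 + (ys - y)^2)) >= config$site_min_sep_um) {
        xs <- c(xs, x); ys <- c(ys, y); placed <- TRUE; break
      }
    }
    if (!placed)
      stop("could not place ", n, " sites at min separation ",
           config$site_min_sep_um, " um; reduce n_sites or the separation")
  }
  data.frame(site_id = seq_len(n), x_um = xs, y_um = ys)
}

#' Simulate ground-truth puff times and channel counts
#'
#' For each site, puff onsets follow a homogeneous Poisson process at its
#' post-flash rate, starting `flash_time_s + Exp(latency_scale_s)`. Each puff
#' draws its channel count from the configured distribution; all channels
#' are open at the sampled peak (the first frame at or after the end of the
#' linear rise) and then close independently after exponential dwells of
#' mean `open_dwell_ms`, producing a descending staircase. Anchoring the
#' dwell clock to the sampled peak frame guarantees the rendered trace
#' contains at least one full-amplitude sample per puff.
#'
#' Uses the current RNG state (see [place_sites()]).
#'
#' @param config A [sim_config()].
#' @param sites Data frame from [place_sites()].
#' @return A `ground_truth` list: `sites`, `puffs` (data.frame `puff_id`,
#'   `site_id`, `onset_s`, `peak_s`, `n_channels`), `closures` (list of
#'   per-puff closure-time vectors, seconds, absolute movie time), and
#'   `global_onset_s` (`NA` unless a global rise is configured).
#' @export
simulate_puff_train <- function(config, sites) {
  stopifnot(inherits(config, "sim_config"))
  rates <- rep(config$puff_rate_hz, length.out = max(1L, nrow(sites)))
  rise_s <- config$rise_ms / 1000
  dwell_s <- config$open_dwell_ms / 1000
  dt <- config$dt_s
  puffs <- list(); closures <- list(); pid <- 0L
  for (i in seq_len(nrow(sites))) {
    rate <- rates[i]
    if (rate <= 0) next
    t0 <- config$flash_time_s +
      if (config$latency_scale_s > 0) rexp(1, 1 / config$latency_scale_s) else 0
    t <- t0
    repeat {
      t <- t + rexp(1, rate)
      if (t >= config$duration_s) break
      n <- sample.int(config$channel_kmax, 1L, prob = config$channel_pmf)
      # first sampled frame at/after full amplitude; frame k is at (k-1)*dt
      peak_s <- dt * ceiling((t + rise_s) / dt - 1e-9)
      cl <- peak_s + if (dwell_s > 0) rexp(n, 1 / dwell_s) else rep(dt / 2, n)
      pid <- pid + 1L
      puffs[[pid]] <- data.frame(puff_id = pid, site_id = sites$site_id[i],
                                 onset_s = t, peak_s = peak_s, n_channels = n)
      closures[[pid]] <- cl
    }
  }
  puffs <- if (length(puffs)) do.call(rbind, puffs) else
    data.frame(puff_id = integer(0), site_id = integer(0), onset_s = numeric(0),
               peak_s = numeric(0), n_channels = integer(0))
  structure(list(sites = sites, puffs = puffs, closures = closures,
                 global_onset_s = config$global_rise$onset_s %||% NA_real_),
            class = "ground_truth")
}

#' Build a ground truth with hand-specified puffs
#'
#' Convenience constructor for controlled experiments: supply puff onsets,
#' channel counts and (optionally) closure times directly instead of drawing
#' them from the Poisson model. Closure times default to exponential dwells
#' after the sampled peak, drawn from the current RNG state.
#'
#' @param config A [sim_config()].
#' @param sites Data frame with `site_id`, `x_um`, `y_um`.
#' @param onsets Numeric vector of puff onset times (s, absolute movie time).
#' @param site_ids Site of each puff (parallel to `onsets`).
#' @param n_channels Channel count of each puff.
#' @param closures Optional list of per-puff closure-time vectors.
#' @return A `ground_truth` list, as from [simulate_puff_train()].
#' @export
make_ground_truth <- function(config, sites, onsets, site_ids, n_channels,
                              closures = NULL) {
  stopifnot(inherits(config, "sim_config"),
            length(onsets) == length(site_ids),
            length(onsets) == length(n_channels))
  dt <- config$dt_s
  rise_s <- config$rise_ms / 1000
  dwell_s <- config$open_dwell_ms / 1000
  peak_s <- dt * ceiling((onsets + rise_s) / dt - 1e-9)
  if (is.null(closures)) {
    closures <- lapply(seq_along(onsets), function(i)
      peak_s[i] + if (dwell_s > 0) rexp(n_channels[i], 1 / dwell_s)
                  else rep(dt / 2, n_channels[i]))
  }
  stopifnot(length(closures) == length(onsets))
  ord <- order(onsets)
  puffs <- data.frame(puff_id = seq_along(onsets), site_id = site_ids[ord],
                      onset_s = onsets[ord], peak_s = peak_s[ord],
                      n_channels = as.integer(n_channels[ord]))
  structure(list(sites = sites, puffs = puffs, closures = closures[ord],
                 global_onset_s = config$global_rise$onset_s %||% NA_real_),
            class = "ground_truth")
}

#' Render a ground truth into a fluorescence movie
#'
#' The baseline is `baseline_f0` everywhere. Each open channel at a site
#' adds an isotropic 2-D Gaussian (`psf_sigma_um`) centred on the site,
#' scaled so that its mean over the 11 x 11 pixel measurement ROI centred on
#' the site's nearest pixel equals `unitary_step_dF * baseline_f0` -- i.e.
#' the quantal amplitude is expressed in the ROI-averaged \eqn{\Delta F/F_0}
#' units in which the analysis measures it. During the linear rise the summed
#' signal of all channels ramps from 0 to full amplitude; after the peak the
#' amplitude steps down as channels close. An optional global rise adds a
#' circular plateau wave spreading from a random pixel. Per-pixel noise is
#' applied according to `config$noise` and negative intensities are clipped
#' to zero.
#'
#' Uses the current RNG state for noise and the global-rise origin.
#'
#' @param config A [sim_config()].
#' @param truth A `ground_truth` from [simulate_puff_train()] or
#'   [make_ground_truth()].
#' @return A [ca_movie()] with `flash_frame` set to the first post-flash
#'   frame index.
#' @export
render_movie <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  Y <- config$field_px[1]; X <- config$field_px[2]
  dt <- config$dt_s
  Tn <- round(config$duration_s / dt)
  flash_frame <- as.integer(ceiling(config$flash_time_s / dt - 1e-9)) + 1L
  f0 <- config$baseline_f0
  frames <- array(f0, dim = c(Y, X, Tn))
  rise_s <- config$rise_ms / 1000
  sig_px <- config$psf_sigma_um / config$pixel_um
  rp <- max(6L, as.integer(ceiling(5 * sig_px)) + 5L)  # patch half-width, px

  # per-site normalized patches: mean over the 11x11 ROI at the site == 1
  site_patch <- vector("list", nrow(truth$sites))
  for (i in seq_len(nrow(truth$sites))) {
    cy <- um_to_px(truth$sites$y_um[i], config$pixel_um)
    cx <- um_to_px(truth$sites$x_um[i], config$pixel_um)
    rows <- max(1L, cy - rp):min(Y, cy + rp)
    cols <- max(1L, cx - rp):min(X, cx + rp)
    dy <- px_center_um(rows, config$pixel_um) - truth$sites$y_um[i]
    dx <- px_center_um(cols, config$pixel_um) - truth$sites$x_um[i]
    k <- exp(-(outer(dy^2, dx^2, `+`)) / (2 * config$psf_sigma_um^2))
    roi_rows <- max(1L, cy - 5L):min(Y, cy + 5L)
    roi_cols <- max(1L, cx - 5L):min(X, cx + 5L)
    s_roi <- sum(k[match(roi_rows, rows), match(roi_cols, cols)])
    npx <- length(roi_rows) * length(roi_cols)
    site_patch[[i]] <- list(rows = rows, cols = cols, k = k * (npx / s_roi))
  }

  # puff contributions
  for (p in seq_len(nrow(truth$puffs))) {
    pf <- truth$puffs[p, ]
    cl <- truth$closures[[p]]
    sp <- site_patch[[match(pf$site_id, truth$sites$site_id)]]
    i1 <- as.integer(ceiling(pf$onset_s / dt - 1e-9)) + 1L
    i2 <- min(Tn, as.integer(floor(max(cl) / dt + 1e-9)) + 1L)
    if (i1 > Tn || i2 < i1) next
    for (i in i1:i2) {
      t <- (i - 1) * dt
      amp <- if (t < pf$onset_s) 0
        else if (rise_s > 0 && t < pf$onset_s + rise_s)
          pf$n_channels * (t - pf$onset_s) / rise_s
        else if (t <= pf$peak_s) pf$n_channels
        else sum(cl > t)
      if (amp <= 0) next
      frames[sp$rows, sp$cols, i] <- frames[sp$rows, sp$cols, i] +
        amp * config$unitary_step_dF * f0 * sp$k
    }
  }

  # global rise: circular plateau wave from a random pixel
  if (!is.null(config$global_rise)) {
    gr <- config$global_rise
    oy <- px_center_um(sample.int(Y, 1L), config$pixel_um)
    ox <- px_center_um(sample.int(X, 1L), config$pixel_um)
    dist <- sqrt(outer((px_center_um(seq_len(Y), config$pixel_um) - oy)^2,
                       (px_center_um(seq_len(X), config$pixel_um) - ox)^2, `+`))
    i0 <- as.integer(ceiling(gr$onset_s / dt - 1e-9)) + 1L
    for (i in max(1L, i0):Tn) {
      r <- gr$wave_speed_um_s * ((i - 1) * dt - gr$onset_s)
      if (r < 0) next
      mask <- dist <= r
      if (any(mask)) {
        fr <- frames[, , i]
        fr[mask] <- fr[mask] + gr$plateau_dF * f0
        frames[, , i] <- fr
      }
    }
  }

  frames <- switch(config$noise$model,
    none = frames,
    gaussian = frames + rnorm(length(frames), 0,
                              (config$noise$sd_frac %||% 0.02) * f0),
    poisson = {
      g <- config$noise$gain %||% 1
      array(rpois(length(frames), pmax(frames, 0) / g) * g, dim = dim(frames))
    })
  frames[frames < 0] <- 0
  ca_movie(frames, dt_s = dt, pixel_um = config$pixel_um,
           flash_frame = flash_frame)
}

#' Simulate a complete annotated movie
#'
#' Seeds the RNG from `config$seed`, places sites, draws the puff train and
#' renders the movie; identical configs therefore yield bit-identical movies
#' and ground truths.
#'
#' @param config A [sim_config()].
#' @return `list(movie, truth, config)`.
#' @export
simulate_movie <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sites <- place_sites(config)
  truth <- simulate_puff_train(config, sites)
  movie <- render_movie(config, truth)
  list(movie = movie, truth = truth, config = config)
}

#' Write / read a ground-truth sidecar as JSON
#'
#' The sidecar stores site positions, per-puff records with closure times,
#' the global-rise onset and an echo of the generating configuration, so a
#' movie file and its sidecar are a self-contained test fixture.
#'
#' @param truth A `ground_truth`.
#' @param path Output JSON path.
#' @param config Optional [sim_config()] to echo into the sidecar.
#' @return `path` invisibly (write) or a `ground_truth` (read).
#' @export
write_ground_truth <- function(truth, path, config = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  obj <- list(sites = truth$sites, puffs = truth$puffs,
              closures = truth$closures,
              global_onset_s = truth$global_onset_s,
              config = if (!is.null(config)) unclass(config) else NULL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  closures <- obj$closures
  if (is.null(closures)) closures <- list()
  if (!is.list(closures)) closures <- as.list(closures)
  structure(list(sites = as.data.frame(obj$sites),
                 puffs = as.data.frame(obj$puffs),
                 closures = lapply(closures, as.numeric),
                 global_onset_s = obj$global_onset_s %||% NA_real_),
            class = "ground_truth")
}
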