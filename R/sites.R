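#' Assign puffs to fixed release sites
#'
#' Puffs are taken to arise at different sites when their centroids are more
#' than `sep_um` apart (0.96 um by default). Assignment is greedy and
#' chronological in order of the peak frame: each event joins the existing
#' site whose current centroid is nearest and at most `sep_um` away,
#' otherwise it founds a new site; a site's centroid is the running mean of
#' its members' centroids. A site's first-detection time is the earliest
#' supra-threshold onset among its members, in seconds after the flash.
#'
#' @param events List of `puff_event` objects with centroids.
#' @param sep_um Separation criterion in micrometres.
#' @return `list(sites, events)`: `sites` is a data.frame with `site_id`,
#'   `x_um`, `y_um`, `n_puffs`, `first_detection_s`; `events` is the input
#'   list with `site_id` filled in.
#' @export
assign_sites <- function(events, sep_um = 0.96) {
  if (!length(events))
    return(list(sites = data.frame(site_id = integer(0), x_um = numeric(0),
                                   y_um = numeric(0), n_puffs = integer(0),
                                   first_detection_s = numeric(0)),
                events = events))
  ord <- order(vapply(events, function(e) e$t_peak_frame, integer(1)))
  sx <- numeric(0); sy <- numeric(0); sn <- integer(0); sfirst <- numeric(0)
  for (i in ord) {
    e <- events[[i]]
    onset_s <- (e$onset_frame - e$flash_frame) * e$dt_s
    j <- NA_integer_
    if (length(sx)) {
      dd <- sqrt((sx - e$centroid_x_um)^2 + (sy - e$centroid_y_um)^2)
      jmin <- which.min(dd)
      if (dd[jmin] <= sep_um) j <- jmin
    }
    if (is.na(j)) {
      sx <- c(sx, e$centroid_x_um); sy <- c(sy, e$centroid_y_um)
      sn <- c(sn, 1L); sfirst <- c(sfirst, onset_s)
      j <- length(sx)
    } else {
      sx[j] <- (sx[j] * sn[j] + e$centroid_x_um) / (sn[j] + 1L)
      sy[j] <- (sy[j] * sn[j] + e$centroid_y_um) / (sn[j] + 1L)
      sn[j] <- sn[j] + 1L
      sfirst[j] <- min(sfirst[j], onset_s)
    }
    events[[i]]$site_id <- j
  }
  list(sites = data.frame(site_id = seq_along(sx), x_um = sx, y_um = sy,
                          n_puffs = sn, first_detection_s = sfirst),
       events = events)
}

#' Per-interval counts of newly discovered release sites
#'
#' Divides the observation window into successive bins of width `bin_s` and
#' counts the sites whose first detection falls in each bin.
#'
#' @param sites Data frame from [assign_sites()] (needs
#'   `first_detection_s`).
#' @param bin_s Bin width in seconds (`> 0`).
#' @param window_s `c(start, end)` of the observation window, in seconds
#'   after the flash.
#' @return A `discovery_curve`: list with `bin_s`, `window_s`,
#'   `new_site_counts`, `bin_centers_s` and placeholders for the fit
#'   (`t_half_s`, `amplitude`, `r_squared`, `residuals`, `n_half_lives`,
#'   `coverage_fraction`, `flags`).
#' @export
discovery_curve <- function(sites, bin_s, window_s = c(0, 40)) {
  if (bin_s <= 0) stop("bin_s must be > 0")
  if (window_s[2] <= window_s[1]) stop("window_s must be increasing")
  n_bins <- as.integer(ceiling((window_s[2] - window_s[1]) / bin_s - 1e-9))
  fd <- sites$first_detection_s
  fd <- fd[fd >= window_s[1] & fd < window_s[1] + n_bins * bin_s]
  counts <- tabulate(floor((fd - window_s[1]) / bin_s) + 1L, nbins = n_bins)
  structure(list(bin_s = bin_s, window_s = window_s,
                 new_site_counts = counts,
                 bin_centers_s = window_s[1] + (seq_len(n_bins) - 0.5) * bin_s,
                 t_half_s = NA_real_, amplitude = NA_real_,
                 r_squared = NA_real_, residuals = NULL,
                 n_half_lives = NA_real_, coverage_fraction = NA_real_,
                 flags = character(0)),
            class = "discovery_curve")
}

#' Fit the mono-exponential decline of new-site discovery
#'
#' Least-squares fit of `c_i = A * exp(-ln 2 * t_i / t_half)` to the
#' per-bin counts of newly discovered sites at the bin-centre times,
#' including zero-count trailing bins. Non-decaying counts are flagged and
#' reported with `t_half_s = Inf`.
#'
#' @param curve A [discovery_curve()].
#' @param weighted Use Poisson-motivated weights `1/max(c_i, 1)` instead of
#'   unweighted least squares.
#' @return The curve with `t_half_s`, `amplitude`, `r_squared` and
#'   `residuals` filled.
#' @export
fit_discovery_halftime <- function(curve, weighted = FALSE) {
  stopifnot(inherits(curve, "discovery_curve"))
  cts <- curve$new_site_counts
  tt <- curve$bin_centers_s
  if (length(cts) < 3L) stop("need >= 3 bins to fit a half-time")
  if (sum(cts > 0) < 1L) stop("all bins are empty")
  pos <- cts > 0
  flag_nondecay <- function(curve) {
    curve$flags <- add_flag(curve$flags, "non_decaying")
    curve$t_half_s <- Inf
    curve
  }
  if (sum(pos) < 2L) {
    # a single occupied bin cannot constrain a slope
    curve$flags <- add_flag(curve$flags, "single_occupied_bin")
    curve$t_half_s <- Inf
    return(curve)
  }
  lf <- lm(log(cts[pos]) ~ tt[pos])
  slope <- coef(lf)[2]
  if (!is.finite(slope) || slope >= -1e-12) return(flag_nondecay(curve))
  start <- list(A = unname(exp(coef(lf)[1])), th = unname(-log(2) / slope))
  w <- if (weighted) 1 / pmax(cts, 1) else rep(1, length(cts))
  fit <- tryCatch(
    minpack.lm::nlsLM(cts ~ A * exp(-log(2) * tt / th), start = start,
                      weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(flag_nondecay(curve))
  cf <- coef(fit)
  if (!is.finite(cf[["th"]]) || cf[["th"]] <= 0) return(flag_nondecay(curve))
  pred <- cf[["A"]] * exp(-log(2) * tt / cf[["th"]])
  ss_res <- sum((cts - pred)^2)
  ss_tot <- sum((cts - mean(cts))^2)
  curve$t_half_s <- unname(cf[["th"]])
  curve$amplitude <- unname(cf[["A"]])
  curve$r_squared <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  curve$residuals <- cts - pred
  curve
}

#' Expected fraction of release sites discovered within a window
#'
#' With new-site discovery declining mono-exponentially with half-time
#' `t_half_s`, an observation window of `observed_window_s` spans
#' `n = observed_window_s / t_half_s` half-lives and is expected to reveal
#' `100 * (1 - 2^-n)` percent of all sites.
#'
#' @param t_half_s Discovery half-time in seconds (`> 0`).
#' @param observed_window_s Observation window in seconds (`>= 0`).
#' @return `list(n_half_lives, coverage_percent)`.
#' @examples
#' coverage_fraction(5.53, 40)  # slowest printed half-time, full recording
#' coverage_fraction(2.01, 10)  # WT half-time, typical effective recording
#' @export
coverage_fraction <- function(t_half_s, observed_window_s) {
  if (!is.numeric(t_half_s) || length(t_half_s) != 1L || is.na(t_half_s) ||
      t_half_s <= 0)
    stop("t_half_s must be a single positive number")
  if (observed_window_s < 0) stop("observed_window_s must be >= 0")
  n <- observed_window_s / t_half_s
  list(n_half_lives = n, coverage_percent = 100 * (1 - 2^(-n)))
}

#' Per-cell summary of the puff analysis
#'
#' @param events List of `puff_event` objects (already truncated at the
#'   global rise, if any, and assigned to sites).
#' @param sites Sites data frame from [assign_sites()].
#' @param movie The analysed [ca_movie()].
#' @param global_onset_frame Onset frame of the global rise from
#'   [detect_global_rise()], or `NULL`.
#' @return A `cell_summary`: list with `latency_first_puff_s` (onset of the
#'   first event after the flash; `NA` with no events),
#'   `puff_frequency_hz` (puffs per second of effective recording),
#'   `total_puffs`, `total_sites`, `global_rise`, `global_onset_s`,
#'   `effective_recording_s` and `flags` (flagged when the effective
#'   recording is shorter than 2 s).
#' @export
summarize_cell <- function(events, sites, movie, global_onset_frame = NULL) {
  stopifnot(inherits(movie, "ca_movie"))
  Tn <- dim(movie$frames)[3]
  end_frame <- global_onset_frame %||% (Tn + 1L)
  eff <- (end_frame - movie$flash_frame) * movie$dt_s
  flags <- character(0)
  if (eff < 2) flags <- add_flag(flags, "short_effective_recording")
  latency <- if (length(events)) {
    min(vapply(events, function(e)
      (e$onset_frame - e$flash_frame) * e$dt_s, numeric(1)))
  } else NA_real_
  structure(list(
    latency_first_puff_s = latency,
    puff_frequency_hz = if (eff > 0) length(events) / eff else NA_real_,
    total_puffs = length(events),
    total_sites = nrow(sites),
    global_rise = !is.null(global_onset_frame),
    global_onset_s = if (!is.null(global_onset_frame))
      (global_onset_frame - movie$flash_frame) * movie$dt_s else NA_real_,
    effective_recording_s = eff,
    flags = flags), class = "cell_summary")
}
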