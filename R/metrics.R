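#' Reference fluorescence before and after a puff
#'
#' The reference level F_pre is the mean of the ROI trace over the
#' `n_ref_frames` frames immediately before the event's supra-threshold
#' onset and the `n_ref_frames` immediately after its end (pooled). If only
#' one side is available within the event window the mean is one-sided and
#' the event is flagged; with no reference frames at all, F_pre falls back
#' to the first trace value and the event is flagged `"no_reference"`.
#'
#' Also fills `amplitude_dF = f_peak - f_pre`.
#'
#' @param event A `puff_event`.
#' @param n_ref_frames Reference frames on each side (default 10).
#' @return The event with `f_pre` and `amplitude_dF` set.
#' @export
compute_reference <- function(event, n_ref_frames = 10L) {
  stopifnot(inherits(event, "puff_event"))
  ws <- event$window[["start"]]
  pre_g <- (event$onset_frame - n_ref_frames):(event$onset_frame - 1L)
  post_g <- (event$end_frame + 1L):(event$end_frame + n_ref_frames)
  pre <- pre_g[pre_g >= ws & pre_g <= event$window[["end"]]] - ws + 1L
  post <- post_g[post_g >= ws & post_g <= event$window[["end"]]] - ws + 1L
  vals <- event$trace[c(pre, post)]
  if (!length(vals)) {
    event$f_pre <- event$trace[1]
    event$flags <- add_flag(event$flags, "no_reference")
  } else {
    if (!length(pre) || !length(post))
      event$flags <- add_flag(event$flags, "one_sided_reference")
    event$f_pre <- mean(vals)
  }
  event$amplitude_dF <- event$f_peak - event$f_pre
  if (event$amplitude_dF < 0)
    event$flags <- add_flag(event$flags, "negative_amplitude")
  event
}

# linear-interpolation crossing time between frames i and i+1 (frame units,
# 1-based within the trace); level assumed strictly between the two samples
cross_time <- function(trace, i, level) {
  i + (level - trace[i]) / (trace[i + 1L] - trace[i])
}

#' Puff kinetics: 20-100% rise, 100-20% decay, duration at half-maximum
#'
#' Thresholds are placed at `f_pre + 0.2 * amplitude` and
#' `f_pre + 0.5 * amplitude`. The rise time runs from the last upward
#' crossing of the 20% level before the peak to the peak sample (the peak is
#' a sample, not a crossing, so no interpolation at the top); the decay time
#' from the peak to the first downward crossing of the 20% level after it;
#' the duration at half-maximal amplitude between the last upward and first
#' downward crossings of the 50% level bracketing the peak. Crossing times
#' are linearly interpolated between frames. A trace that never returns
#' below a level inside the window is flagged right-censored and the
#' available extent is reported; similarly left-censored rises.
#'
#' If the window contains a secondary peak (another local maximum above the
#' 50% level separated from the main peak by a dip below it), kinetics are
#' computed on the highest peak and the event is flagged
#' `"secondary_peak"`.
#'
#' @param event A `puff_event` with `f_pre` and a positive `amplitude_dF`.
#' @return The event with `rise_ms`, `decay_ms`, `fwhm_ms` set.
#' @export
compute_kinetics <- function(event) {
  stopifnot(inherits(event, "puff_event"))
  if (is.na(event$amplitude_dF) || event$amplitude_dF <= 0) {
    event$flags <- add_flag(event$flags, "kinetics_skipped")
    return(event)
  }
  tr <- event$trace
  dt_ms <- event$dt_s * 1000
  ws <- event$window[["start"]]
  p <- event$t_peak_frame - ws + 1L
  L20 <- event$f_pre + 0.2 * event$amplitude_dF
  L50 <- event$f_pre + 0.5 * event$amplitude_dF

  up_cross <- function(level) {
    # last upward crossing of `level` before the peak
    i <- p - 1L
    while (i >= 1L && tr[i] > level) i <- i - 1L
    if (i < 1L) return(NA_real_)
    cross_time(tr, i, level)
  }
  down_cross <- function(level) {
    # first downward crossing of `level` after the peak
    i <- p
    n <- length(tr)
    while (i < n && tr[i + 1L] > level) i <- i + 1L
    if (i >= n) return(NA_real_)
    cross_time(tr, i, level)
  }

  t20u <- up_cross(L20); t50u <- up_cross(L50)
  t20d <- down_cross(L20); t50d <- down_cross(L50)
  if (is.na(t20u)) {
    event$flags <- add_flag(event$flags, "rise_censored")
    t20u <- 1
  }
  if (is.na(t50u)) t50u <- 1
  if (is.na(t20d)) {
    event$flags <- add_flag(event$flags, "decay_censored")
    t20d <- length(tr)
  }
  if (is.na(t50d)) t50d <- length(tr)
  event$rise_ms <- (p - t20u) * dt_ms
  event$decay_ms <- (t20d - p) * dt_ms
  event$fwhm_ms <- (t50d - t50u) * dt_ms

  # secondary peaks: another sample above the 50% level beyond a dip below it
  above <- tr > L50
  if (any(above)) {
    runs <- rle(above)
    if (sum(runs$values) > 1L)
      event$flags <- add_flag(event$flags, "secondary_peak")
  }
  event
}

# Binary segmentation of a numeric vector into plateaus: recursively split
# where the within-segment sum of squares drops by more than `penalty`.
binseg_breaks <- function(x, penalty) {
  n <- length(x)
  breaks <- integer(0)
  sse <- function(lo, hi) {
    v <- x[lo:hi]
    sum(v * v) - sum(v)^2 / length(v)
  }
  recurse <- function(lo, hi) {
    n_seg <- hi - lo + 1L
    if (n_seg < 2L) return()
    v <- x[lo:hi]
    cs <- cumsum(v); css <- cumsum(v * v)
    k <- seq_len(n_seg - 1L)
    sse_l <- css[k] - cs[k]^2 / k
    sse_r <- (css[n_seg] - css[k]) - (cs[n_seg] - cs[k])^2 / (n_seg - k)
    tot <- css[n_seg] - cs[n_seg]^2 / n_seg
    gain <- tot - (sse_l + sse_r)
    kbest <- which.max(gain)
    if (gain[kbest] > penalty) {
      brk <- lo + kbest - 1L
      breaks <<- c(breaks, brk)
      recurse(lo, brk)
      recurse(brk + 1L, hi)
    }
  }
  recurse(1L, n)
  sort(breaks)
}

#' Estimate the unitary fluorescence step from a puff's falling phase
#'
#' The decay segment (trace peak to window end) is segmented into plateaus
#' by binary segmentation minimizing within-plateau variance, with a
#' BIC-like penalty scaled by a robust noise estimate (MAD of the first
#' differences); a noise-free k-step staircase therefore returns exactly its
#' k drops. Plateaus shorter than `min_plateau` frames are merged into the
#' neighbour with the closer mean, and adjacent plateaus that do not
#' strictly decrease are merged, so the reported levels form a descending
#' staircase. The unitary step is the median of consecutive drops.
#'
#' @param event A `puff_event` (or a bare numeric trace via `trace`).
#' @param min_plateau Minimum plateau length in frames (default 2).
#' @param penalty Split penalty; by default `3 * sigma^2 * log(n)` with
#'   `sigma` the MAD-based noise estimate (floored at a tiny positive value
#'   so noise-free staircases split on exact variance reductions only).
#' @param trace Optional numeric vector to segment directly, overriding the
#'   event's decay segment.
#' @return A `step_estimate`: list with `step_levels`, `plateau_lengths`,
#'   `unitary_dF` (median consecutive drop, `NA` when fewer than 2
#'   plateaus), `n_steps` and `flags`.
#' @export
estimate_unitary_step <- function(event, min_plateau = 2L, penalty = NULL,
                                  trace = NULL) {
  if (is.null(trace)) {
    stopifnot(inherits(event, "puff_event"))
    p <- event$t_peak_frame - event$window[["start"]] + 1L
    seg <- event$trace[p:length(event$trace)]
  } else {
    seg <- as.numeric(trace)
  }
  if (length(seg) < 4L)
    stop("decay segment has ", length(seg), " frames; need >= 4")
  flags <- character(0)
  if (is.null(penalty)) {
    sigma <- mad(diff(seg)) / sqrt(2)
    penalty <- max(3 * sigma^2 * log(length(seg)), 1e-12)
  }
  brk <- binseg_breaks(seg, penalty)
  bounds <- c(0L, brk, length(seg))
  lens <- diff(bounds)
  levels <- vapply(seq_along(lens), function(i)
    mean(seg[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
  if (mean(lens) < min_plateau)
    flags <- add_flag(flags, "short_plateaus")
  # merge short plateaus into the neighbour with the closer mean
  while (length(lens) > 1L && any(lens < min_plateau)) {
    i <- which(lens < min_plateau)[which.min(lens[lens < min_plateau])]
    j <- if (i == 1L) 2L
         else if (i == length(lens)) i - 1L
         else if (abs(levels[i - 1L] - levels[i]) <=
                  abs(levels[i + 1L] - levels[i])) i - 1L else i + 1L
    a <- min(i, j); b <- max(i, j)
    levels[a] <- (levels[a] * lens[a] + levels[b] * lens[b]) / (lens[a] + lens[b])
    lens[a] <- lens[a] + lens[b]
    levels <- levels[-b]; lens <- lens[-b]
  }
  # enforce a strictly decreasing staircase
  i <- 1L
  while (i < length(levels)) {
    if (levels[i + 1L] >= levels[i]) {
      levels[i] <- (levels[i] * lens[i] + levels[i + 1L] * lens[i + 1L]) /
        (lens[i] + lens[i + 1L])
      lens[i] <- lens[i] + lens[i + 1L]
      levels <- levels[-(i + 1L)]; lens <- lens[-(i + 1L)]
      if (i > 1L) i <- i - 1L
    } else i <- i + 1L
  }
  n_steps <- length(levels) - 1L
  unitary <- if (n_steps >= 1L) median(-diff(levels)) else NA_real_
  if (n_steps < 1L) flags <- add_flag(flags, "no_steps")
  structure(list(step_levels = levels, plateau_lengths = lens,
                 unitary_dF = unitary, n_steps = n_steps, flags = flags),
            class = "step_estimate")
}

#' Number of active channels contributing to a puff
#'
#' Applies the quantal relation N = dF / unitary_dF, where dF is the puff's
#' ROI-averaged amplitude F_peak - F_pre and unitary_dF the mean unitary
#' fluorescence step (0.101 by default). The continuous estimate is stored
#' in `n_channels`; `n_channels_round = max(1, round(N))` is reported
#' alongside for histograms, except that a zero (or negative) amplitude
#' reports 0 with a flag.
#'
#' @param event A `puff_event` with `amplitude_dF` computed.
#' @param unitary_dF Unitary step in dF/F0 units (`> 0`).
#' @return The event with `n_channels` and `n_channels_round` set.
#' @export
count_channels <- function(event, unitary_dF = 0.101) {
  stopifnot(inherits(event, "puff_event"))
  if (!is.numeric(unitary_dF) || length(unitary_dF) != 1L || unitary_dF <= 0)
    stop("unitary_dF must be a single positive number")
  if (is.na(event$amplitude_dF)) stop("amplitude_dF not computed; ",
                                      "run compute_reference() first")
  event$n_channels <- event$amplitude_dF / unitary_dF
  if (event$amplitude_dF <= 0) {
    event$n_channels_round <- 0L
    event$flags <- add_flag(event$flags, "zero_amplitude")
  } else {
    event$n_channels_round <- max(1L, as.integer(round(event$n_channels)))
  }
  event
}

#' Pool per-puff unitary step estimates
#'
#' Averages the unitary-step estimates of puffs with at least one resolved
#' step, as done when calibrating the quantal amplitude from a sample of
#' puffs across cells.
#'
#' @param estimates List of `step_estimate` objects.
#' @return `list(unitary_dF, sem, n)` - mean, standard error of the mean and
#'   the number of contributing puffs.
#' @export
pool_unitary_step <- function(estimates) {
  if (!length(estimates)) stop("no step estimates supplied")
  vals <- vapply(estimates, function(e) {
    stopifnot(inherits(e, "step_estimate")); e$unitary_dF
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no estimate has a resolved step (n_steps >= 1)")
  list(unitary_dF = mean(vals),
       sem = if (length(vals) > 1L) sd(vals) / sqrt(length(vals)) else 0,
       n = length(vals))
}
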