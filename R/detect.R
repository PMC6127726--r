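#' Per-pixel baseline statistics from the pre-flash frames
#'
#' Averages the last `n_baseline_frames` frames before the flash to give a
#' baseline fluorescence F0 and its standard deviation (population s.d.) for
#' each pixel. If fewer pre-flash frames are available, all of them are used
#' with a warning.
#'
#' @param movie A [ca_movie()].
#' @param n_baseline_frames Number of pre-flash frames to use (default 500,
#'   about 2.7 s at 188 Hz).
#' @return `list(f0_map, sd_map, n_frames)` with `f0_map`, `sd_map` matrices
#'   matching the frame shape.
#' @export
compute_baseline <- function(movie, n_baseline_frames = 500L) {
  stopifnot(inherits(movie, "ca_movie"))
  pre <- movie$flash_frame - 1L
  if (pre < 1L) stop("no pre-flash frames: flash_frame = ", movie$flash_frame)
  n <- min(as.integer(n_baseline_frames), pre)
  if (n < n_baseline_frames)
    warning("only ", n, " pre-flash frames available (requested ",
            n_baseline_frames, "); using all of them")
  d <- dim(movie$frames)
  idx <- (movie$flash_frame - n):(movie$flash_frame - 1L)
  m <- matrix(movie$frames[, , idx], nrow = d[1] * d[2], ncol = n)
  mu <- rowMeans(m)
  va <- rowMeans(m * m) - mu * mu
  list(f0_map = matrix(mu, d[1], d[2]),
       sd_map = matrix(sqrt(pmax(va, 0)), d[1], d[2]),
       n_frames = n)
}

#' Normalize a movie to z-like [(F/F0) - 1]/s.d. units
#'
#' Each frame is converted to \eqn{((F/F_0) - 1)/\sigma} per pixel, where
#' \eqn{\sigma} is the baseline s.d. expressed in F/F0 units
#' (`sd_map / f0_map`) and floored at `sd_floor` so that dead pixels do not
#' produce infinities; the result is then spatially Gaussian-filtered
#' per frame (no temporal filtering). Pixels with `f0 <= 0` are masked
#' (z = 0) and counted in the returned mask report.
#'
#' With `gaussian_sigma_px = 0` the unfiltered arithmetic is returned
#' exactly.
#'
#' @param movie A [ca_movie()].
#' @param f0_map,sd_map Baseline maps from [compute_baseline()].
#' @param gaussian_sigma_px Spatial filter s.d. in pixels (default 1).
#' @param sd_floor Lower bound on the baseline s.d. in F/F0 units.
#' @return An object of class `normalized_stack`: list with `z` (3-D array),
#'   `f0_map`, `sd_map`, `mask` (logical matrix of masked pixels),
#'   `n_masked`, and the calibration (`dt_s`, `pixel_um`, `flash_frame`).
#' @export
normalize_stack <- function(movie, f0_map, sd_map, gaussian_sigma_px = 1.0,
                            sd_floor = 1e-3) {
  stopifnot(inherits(movie, "ca_movie"))
  d <- dim(movie$frames)
  if (!all(dim(f0_map) == d[1:2]) || !all(dim(sd_map) == d[1:2]))
    stop("f0_map/sd_map do not match the frame shape")
  mask <- !(f0_map > 0)
  f0_safe <- ifelse(mask, 1, f0_map)
  sd_eff <- pmax(sd_map / f0_safe, sd_floor)
  z <- (movie$frames / as.vector(f0_safe) - 1) / as.vector(sd_eff)
  if (any(mask)) {
    z <- z * as.vector(!mask)
    message("normalize_stack: masked ", sum(mask), " pixel(s) with f0 <= 0")
  }
  if (gaussian_sigma_px > 0)
    z <- EBImage::imageData(EBImage::gblur(z, sigma = gaussian_sigma_px,
                                           boundary = "replicate"))
  structure(list(z = z, f0_map = f0_map, sd_map = sd_map, mask = mask,
                 n_masked = sum(mask), dt_s = movie$dt_s,
                 pixel_um = movie$pixel_um, flash_frame = movie$flash_frame,
                 gaussian_sigma_px = gaussian_sigma_px, sd_floor = sd_floor),
            class = "normalized_stack")
}

#' Detect Ca2+ puffs by threshold-clustering of the normalized stack
#'
#' Supra-threshold voxels (z > `critical_value`, default 0.8) in the
#' post-flash portion of the stack are grouped into 26-connected components
#' in (y, x, t). Components whose largest single-frame footprint is smaller
#' than `min_px` pixels, or whose temporal extent is shorter than
#' `min_frames` frames, are discarded. Each surviving component yields one
#' event: the brightest voxel fixes the ROI position and the provisional
#' centroid, the frame window is the component's temporal extent padded by
#' `pad_frames` on each side (clipped to the stack), and the trace is the
#' per-frame mean F/F0 over the square ROI (`roi_um`, 11 px at 0.16 um/px)
#' centred on the brightest pixel. Two events at the same location separated
#' by fully sub-threshold frames are distinct events.
#'
#' @param nstack A [normalize_stack()] result.
#' @param movie The movie the stack was built from (raw F for the traces).
#' @param critical_value Detection threshold on z (default 0.8).
#' @param min_px Minimum single-frame footprint in pixels.
#' @param min_frames Minimum temporal extent in frames.
#' @param pad_frames Frames of context kept either side of the event.
#' @param roi_um Side of the square measurement ROI in micrometres; rounded
#'   to an odd number of pixels.
#' @param include_pre_flash Detect in pre-flash frames too (default FALSE).
#' @return A list of `puff_event` objects, ordered chronologically by onset.
#'   Each carries: `event_id`, `centroid_x_um`/`centroid_y_um` (brightest
#'   pixel centre until refined by [fit_centroid()]), `peak_px`
#'   (`c(y, x)`), `zpeak_frame`, `t_peak_frame` (argmax of the ROI trace
#'   within the event extent), `onset_frame`, `end_frame`, `window`,
#'   `trace`, `f_peak`, calibration fields and a `flags` vector.
#' @export
detect_events <- function(nstack, movie, critical_value = 0.8, min_px = 2L,
                          min_frames = 2L, pad_frames = 100L, roi_um = 1.76,
                          include_pre_flash = FALSE) {
  stopifnot(inherits(nstack, "normalized_stack"), inherits(movie, "ca_movie"))
  d <- dim(nstack$z); Y <- d[1]; X <- d[2]; Tn <- d[3]
  from <- if (include_pre_flash) 1L else nstack$flash_frame
  sel <- which(nstack$z > critical_value)
  if (length(sel)) {
    tix <- ((sel - 1L) %/% (Y * X)) + 1L
    sel <- sel[tix >= from]
  }
  if (!length(sel)) return(list())

  lin <- sel - 1L
  vy <- lin %% Y + 1L
  rest <- lin %/% Y
  vx <- rest %% X + 1L
  vt <- rest %/% X + 1L
  zv <- nstack$z[sel]

  # 26-connectivity: 13 forward offsets suffice for an undirected graph
  offs <- expand.grid(dy = -1:1, dx = -1:1, dt = -1:1)
  offs <- offs[offs$dt > 0 | (offs$dt == 0 & (offs$dx > 0 |
            (offs$dx == 0 & offs$dy > 0))), ]
  ei <- integer(0); ej <- integer(0)
  for (r in seq_len(nrow(offs))) {
    dy <- offs$dy[r]; dx <- offs$dx[r]; dtt <- offs$dt[r]
    ok <- vy + dy >= 1L & vy + dy <= Y & vx + dx >= 1L & vx + dx <= X &
          vt + dtt >= from & vt + dtt <= Tn
    if (!any(ok)) next
    nbr <- sel[ok] + dy + dx * Y + dtt * (Y * X)
    mm <- match(nbr, sel)
    hit <- !is.na(mm)
    ei <- c(ei, which(ok)[hit]); ej <- c(ej, mm[hit])
  }
  g <- igraph::make_empty_graph(n = length(sel), directed = FALSE)
  if (length(ei))
    g <- igraph::add_edges(g, rbind(ei, ej))
  memb <- igraph::components(g)$membership

  roi_px <- as.integer(round(roi_um / nstack$pixel_um))
  if (roi_px %% 2L == 0L) roi_px <- roi_px + 1L
  h <- roi_px %/% 2L

  events <- list()
  for (ids in split(seq_along(sel), memb)) {
    tmin <- min(vt[ids]); tmax <- max(vt[ids])
    if (tmax - tmin + 1L < min_frames) next
    if (max(tabulate(vt[ids] - tmin + 1L)) < min_px) next
    # peak voxel: max z; ties broken by earliest frame, then smallest (row, col)
    o <- ids[order(-zv[ids], vt[ids], vy[ids], vx[ids])][1]
    py <- vy[o]; px <- vx[o]; zpeak_frame <- vt[o]
    ws <- max(1L, tmin - pad_frames); we <- min(Tn, tmax + pad_frames)
    rows <- max(1L, py - h):min(Y, py + h)
    cols <- max(1L, px - h):min(X, px + h)
    flags <- character(0)
    if (length(rows) < roi_px || length(cols) < roi_px)
      flags <- add_flag(flags, "edge_roi")
    sub <- movie$frames[rows, cols, ws:we, drop = FALSE]
    f0r <- nstack$f0_map[rows, cols]
    f0r[!(f0r > 0)] <- NA_real_
    ff <- sub / as.vector(f0r)
    trace <- colMeans(matrix(ff, nrow = length(rows) * length(cols)),
                      na.rm = TRUE)
    ext <- (tmin:tmax) - ws + 1L
    ipk <- which.max(trace[ext])
    t_peak_frame <- tmin + ipk - 1L
    ev <- structure(list(
      event_id = NA_integer_,
      centroid_x_um = px_center_um(px, nstack$pixel_um),
      centroid_y_um = px_center_um(py, nstack$pixel_um),
      peak_px = c(y = py, x = px),
      zpeak_frame = zpeak_frame,
      z_peak = zv[o],
      t_peak_frame = t_peak_frame,
      onset_frame = tmin, end_frame = tmax,
      window = c(start = ws, end = we),
      trace = trace,
      f_peak = trace[ext[ipk]],
      f_pre = NA_real_, amplitude_dF = NA_real_,
      rise_ms = NA_real_, decay_ms = NA_real_, fwhm_ms = NA_real_,
      n_channels = NA_real_, n_channels_round = NA_integer_,
      unitary_dF_local = NA_real_, n_steps = NA_integer_,
      site_id = NA_integer_,
      dt_s = nstack$dt_s, pixel_um = nstack$pixel_um,
      flash_frame = nstack$flash_frame,
      flags = flags), class = "puff_event")
    events[[length(events) + 1L]] <- ev
  }
  if (!length(events)) return(list())
  events <- events[order(vapply(events, function(e) e$onset_frame, integer(1)),
                         vapply(events, function(e) e$t_peak_frame, integer(1)))]
  for (i in seq_along(events)) events[[i]]$event_id <- i
  events
}

#' @export
print.puff_event <- function(x, ...) {
  cat(sprintf(
    "puff_event %s: centroid (%.2f, %.2f) um, peak frame %d, dF=%.3f, N=%.2f%s\n",
    x$event_id, x$centroid_x_um, x$centroid_y_um, x$t_peak_frame,
    x$amplitude_dF %||% NA, x$n_channels %||% NA,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Refine an event centroid by 2-D Gaussian fitting
#'
#' Fits an isotropic 2-D Gaussian plus constant offset to the measurement
#' ROI of the event's peak z-frame by least squares. If the fit fails to
#' converge, returns a non-positive amplitude, or lands outside the ROI, the
#' brightest-pixel centre is retained and the event flagged
#' `"centroid_fit_failed"`.
#'
#' @param event A `puff_event` from [detect_events()].
#' @param nstack The [normalize_stack()] result the event came from.
#' @return The event with `centroid_x_um`/`centroid_y_um` refined.
#' @export
fit_centroid <- function(event, nstack) {
  stopifnot(inherits(event, "puff_event"), inherits(nstack, "normalized_stack"))
  d <- dim(nstack$z); Y <- d[1]; X <- d[2]
  roi_px <- 2L * 5L + 1L
  h <- 5L
  py <- event$peak_px[["y"]]; px <- event$peak_px[["x"]]
  rows <- max(1L, py - h):min(Y, py + h)
  cols <- max(1L, px - h):min(X, px + h)
  img <- nstack$z[rows, cols, event$zpeak_frame]
  df <- data.frame(
    v = as.vector(img),
    yy = rep(px_center_um(rows, nstack$pixel_um), times = length(cols)),
    xx = rep(px_center_um(cols, nstack$pixel_um), each = length(rows)))
  x_rng <- range(df$xx); y_rng <- range(df$yy)
  start <- list(b = min(df$v), A = max(df$v) - min(df$v),
                x0 = px_center_um(px, nstack$pixel_um),
                y0 = px_center_um(py, nstack$pixel_um),
                s = nstack$pixel_um)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ b + A * exp(-((xx - x0)^2 + (yy - y0)^2) / (2 * s^2)),
      data = df, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  ok <- FALSE
  if (!is.null(fit)) {
    cf <- coef(fit)
    half <- nstack$pixel_um / 2
    ok <- is.finite(cf[["x0"]]) && is.finite(cf[["y0"]]) &&
      cf[["A"]] > 0 && abs(cf[["s"]]) > 0 &&
      cf[["x0"]] >= x_rng[1] - half && cf[["x0"]] <= x_rng[2] + half &&
      cf[["y0"]] >= y_rng[1] - half && cf[["y0"]] <= y_rng[2] + half
  }
  if (ok) {
    event$centroid_x_um <- unname(cf[["x0"]])
    event$centroid_y_um <- unname(cf[["y0"]])
  } else {
    event$flags <- add_flag(event$flags, "centroid_fit_failed")
  }
  event
}

#' Detect a global Ca2+ rise
#'
#' Returns the first frame at which at least `area_fraction` of the unmasked
#' pixels exceed `z_level` and remain so for at least `min_duration_s`, or
#' `NULL` if that never happens. Downstream puff analysis is truncated at
#' this frame (the effective recording period).
#'
#' @param nstack A [normalize_stack()] result.
#' @param area_fraction Fraction of the field that must be supra-threshold.
#' @param z_level Threshold on z.
#' @param min_duration_s Minimum persistence of the supra-threshold state.
#' @return Integer frame index, or `NULL`.
#' @export
detect_global_rise <- function(nstack, area_fraction = 0.5, z_level = 0.8,
                               min_duration_s = 0.5) {
  stopifnot(inherits(nstack, "normalized_stack"))
  d <- dim(nstack$z)
  npx <- d[1] * d[2]
  keep <- !as.vector(nstack$mask)
  n_keep <- sum(keep)
  if (n_keep == 0L) return(NULL)
  m <- matrix(nstack$z > z_level, nrow = npx)
  frac <- if (all(keep)) colMeans(m) else colSums(m[keep, , drop = FALSE]) / n_keep
  ok <- frac >= area_fraction
  need <- max(1L, as.integer(ceiling(min_duration_s / nstack$dt_s)))
  if (!any(ok) || need > d[3]) return(NULL)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values & runs$lengths >= need)
  if (!length(cand)) return(NULL)
  starts[cand[1]]
}
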