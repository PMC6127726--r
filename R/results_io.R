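#' Tabulate puff events
#'
#' Flattens a list of `puff_event` objects into the stable column schema
#' written to `events.csv`. All times are seconds relative to the flash.
#'
#' @param events List of `puff_event` objects.
#' @return A data.frame with columns `event_id`, `site_id`,
#'   `centroid_x_um`, `centroid_y_um`, `t_peak_s`, `amplitude_dF`,
#'   `rise_ms`, `decay_ms`, `fwhm_ms`, `n_channels`, `n_channels_round`,
#'   `unitary_dF_local`, `f_peak`, `f_pre`, `onset_s`, `flags`
#'   (comma-separated).
#' @export
events_table <- function(events) {
  cols <- c("event_id", "site_id", "centroid_x_um", "centroid_y_um",
            "t_peak_s", "amplitude_dF", "rise_ms", "decay_ms", "fwhm_ms",
            "n_channels", "n_channels_round", "unitary_dF_local",
            "f_peak", "f_pre", "onset_s", "flags")
  if (!length(events)) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    df$flags <- character(0)
    return(df)
  }
  rows <- lapply(events, function(e) {
    data.frame(
      event_id = e$event_id, site_id = e$site_id,
      centroid_x_um = e$centroid_x_um, centroid_y_um = e$centroid_y_um,
      t_peak_s = (e$t_peak_frame - e$flash_frame) * e$dt_s,
      amplitude_dF = e$amplitude_dF, rise_ms = e$rise_ms,
      decay_ms = e$decay_ms, fwhm_ms = e$fwhm_ms,
      n_channels = e$n_channels, n_channels_round = e$n_channels_round,
      unitary_dF_local = e$unitary_dF_local,
      f_peak = e$f_peak, f_pre = e$f_pre,
      onset_s = (e$onset_frame - e$flash_frame) * e$dt_s,
      flags = paste(e$flags, collapse = ","))
  })
  do.call(rbind, rows)
}

#' Write analysis outputs to a directory
#'
#' Writes `events.csv` (one row per puff, schema of [events_table()]),
#' `sites.csv` (`site_id`, `x_um`, `y_um`, `n_puffs`, `first_detection_s`)
#' and `summary.json` (the cell summary plus the discovery curve, if
#' fitted). CSV files are RFC 4180, UTF-8, '.' decimal.
#'
#' @param events List of `puff_event` objects.
#' @param sites Sites data frame from [assign_sites()].
#' @param summary A `cell_summary` from [summarize_cell()].
#' @param out_dir Output directory (created if needed).
#' @param discovery Optional `discovery_curve` to embed in the summary.
#' @return Named character vector of the paths written.
#' @export
write_results <- function(events, sites, summary, out_dir, discovery = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2L) != 0L)
    stop("cannot write to directory: ", out_dir)
  ev_path <- file.path(out_dir, "events.csv")
  si_path <- file.path(out_dir, "sites.csv")
  su_path <- file.path(out_dir, "summary.json")
  write.csv(events_table(events), ev_path, row.names = FALSE,
            fileEncoding = "UTF-8")
  write.csv(sites, si_path, row.names = FALSE, fileEncoding = "UTF-8")
  obj <- unclass(summary)
  if (!is.null(discovery))
    obj$discovery <- unclass(discovery)[c("bin_s", "window_s",
      "new_site_counts", "bin_centers_s", "t_half_s", "amplitude",
      "r_squared", "n_half_lives", "coverage_fraction", "flags")]
  jsonlite::write_json(obj, su_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  c(events = ev_path, sites = si_path, summary = su_path)
}
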