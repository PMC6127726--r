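#' Pipeline configuration
#'
#' A single structured configuration holding every tunable of the simulator
#' and the analysis, plus the run seed. Round-trips losslessly through YAML;
#' unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param simulate Named list of [sim_config()] arguments.
#' @param analysis Named list of [analysis_params()] arguments.
#' @param seed Run seed; overrides `simulate$seed` when given.
#' @return A list of class `pipeline_config` with elements `simulate`
#'   (a `sim_config`), `analysis` (an `analysis_params`) and `seed`.
#' @export
pipeline_config <- function(simulate = list(), analysis = list(), seed = NULL) {
  check_keys <- function(given, allowed, where) {
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stop("unknown ", where, " key(s): ", paste(bad, collapse = ", "))
  }
  check_keys(simulate, names(formals(sim_config)), "simulate")
  check_keys(analysis, names(formals(analysis_params)), "analysis")
  if (!is.null(seed)) simulate$seed <- as.integer(seed)
  sc <- do.call(sim_config, simulate)
  ap <- do.call(analysis_params, analysis)
  structure(list(simulate = sc, analysis = ap, seed = sc$seed),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A [pipeline_config()].
#' @return A `pipeline_config` (read) or `path` invisibly (write).
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  bad <- setdiff(names(obj), c("simulate", "analysis", "seed"))
  if (length(bad))
    stop("unknown top-level config key(s): ", paste(bad, collapse = ", "))
  sim <- obj$simulate %||% list()
  if (!is.null(sim$field_px)) sim$field_px <- as.integer(unlist(sim$field_px))
  if (!is.null(sim$channel_pmf)) sim$channel_pmf <- as.numeric(unlist(sim$channel_pmf))
  pipeline_config(simulate = sim, analysis = obj$analysis %||% list(),
                  seed = obj$seed)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(list(simulate = unclass(config$simulate),
                        analysis = unclass(config$analysis),
                        seed = config$seed), path)
  invisible(path)
}

# manifest with a config hash so deterministic stages reproduce bit-for-bit
write_manifest <- function(config, out_dir, extra = list()) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(list(simulate = unclass(config$simulate),
                            analysis = unclass(config$analysis),
                            seed = config$seed),
                       tmp, auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- c(list(config_hash = unname(tools::md5sum(tmp)),
                     seed = config$seed,
                     r_version = as.character(getRversion()),
                     package_version =
                       as.character(utils::packageVersion("capuff"))),
                extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Simulate a movie to disk
#'
#' Writes `movie.tif` (16-bit multi-page TIFF), `ground_truth.json` (sites,
#' puffs, closure times, global-rise onset, config echo) and
#' `manifest.json` (config hash, seed, versions) into `out_dir`. Fully
#' deterministic under a fixed config.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Named vector of paths written.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_movie(config$simulate)
  mv <- file.path(out_dir, "movie.tif")
  gt <- file.path(out_dir, "ground_truth.json")
  write_movie(sim$movie, mv)
  write_ground_truth(sim$truth, gt, config = config$simulate)
  write_manifest(config, out_dir,
                 extra = list(flash_frame = sim$movie$flash_frame,
                              n_frames = dim(sim$movie$frames)[3]))
  c(movie = mv, ground_truth = gt,
    manifest = file.path(out_dir, "manifest.json"))
}

#' Analyze a movie file to disk
#'
#' Reads the movie, runs [analyze_movie()] with the configured parameters
#' and writes `events.csv`, `sites.csv`, `summary.json` and
#' `manifest.json` into `out_dir`.
#'
#' @param config A [pipeline_config()] (its `analysis` block is used; the
#'   `simulate` block supplies the calibration defaults when the explicit
#'   arguments are `NULL`).
#' @param movie_path Path to a TIFF stack.
#' @param out_dir Output directory.
#' @param dt_s,pixel_um,flash_frame Calibration for the movie file; default
#'   to the values in `config$simulate`.
#' @param background_roi Optional background rectangle, as in [ca_movie()].
#' @return Named vector of paths written.
#' @export
run_analyze <- function(config, movie_path, out_dir, dt_s = NULL,
                        pixel_um = NULL, flash_frame = NULL,
                        background_roi = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sc <- config$simulate
  dt_s <- dt_s %||% sc$dt_s
  pixel_um <- pixel_um %||% sc$pixel_um
  flash_frame <- flash_frame %||%
    (as.integer(ceiling(sc$flash_time_s / sc$dt_s - 1e-9)) + 1L)
  movie <- read_movie(movie_path, dt_s = dt_s, pixel_um = pixel_um,
                      flash_frame = flash_frame,
                      background_roi = background_roi)
  res <- analyze_movie(movie, config$analysis)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_results(res$events, res$sites, res$summary, out_dir,
                         discovery = res$discovery)
  write_manifest(config, out_dir,
                 extra = list(movie = basename(movie_path),
                              dt_s = dt_s, pixel_um = pixel_um,
                              flash_frame = flash_frame))
  c(paths, manifest = file.path(out_dir, "manifest.json"))
}
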