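#' Construct a calibrated fluorescence movie
#'
#' A movie is a time-ordered stack of grayscale frames with the physical
#' calibration needed by the analysis: the frame interval, the pixel size and
#' the index of the first frame after photolysis of the caged agonist.
#'
#' @param frames 3-D numeric array `[y, x, t]` of non-negative camera
#'   intensities, with at least two frames.
#' @param dt_s Frame interval in seconds (`> 0`).
#' @param pixel_um Pixel edge length in micrometres (`> 0`).
#' @param flash_frame 1-based index of the first post-photolysis frame.
#' @param background_roi Optional rectangle `c(ymin, ymax, xmin, xmax)`
#'   (1-based, inclusive) covering a region outside the cell, used by
#'   [subtract_background()].
#'
#' @return An object of class `ca_movie`: a list with elements `frames`,
#'   `dt_s`, `pixel_um`, `flash_frame` and `background_roi`.
#' @seealso [read_movie()], [write_movie()], [subtract_background()]
#' @export
ca_movie <- function(frames, dt_s, pixel_um, flash_frame, background_roi = NULL) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3-D array [y, x, t]")
  d <- dim(frames)
  if (d[3] < 2L) stop("a movie needs at least 2 frames, got ", d[3])
  if (d[1] < 1L || d[2] < 1L) stop("frame dimensions must be >= 1")
  if (!is.numeric(dt_s) || length(dt_s) != 1L || dt_s <= 0)
    stop("`dt_s` must be a single positive number")
  if (!is.numeric(pixel_um) || length(pixel_um) != 1L || pixel_um <= 0)
    stop("`pixel_um` must be a single positive number")
  flash_frame <- as.integer(flash_frame)
  if (is.na(flash_frame) || flash_frame < 1L || flash_frame > d[3])
    stop("`flash_frame` must lie in [1, ", d[3], "]")
  if (!is.null(background_roi)) {
    background_roi <- as.integer(background_roi)
    if (length(background_roi) != 4L)
      stop("`background_roi` must be c(ymin, ymax, xmin, xmax)")
    if (background_roi[1] < 1L || background_roi[2] > d[1] ||
        background_roi[3] < 1L || background_roi[4] > d[2] ||
        background_roi[1] > background_roi[2] ||
        background_roi[3] > background_roi[4])
      stop("`background_roi` must lie fully inside the frame bounds")
  }
  structure(
    list(frames = frames, dt_s = dt_s, pixel_um = pixel_um,
         flash_frame = flash_frame, background_roi = background_roi),
    class = "ca_movie"
  )
}

#' @export
print.ca_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "ca_movie: %d x %d px, %d frames (%.2f s at %.2f Hz), %.0f nm/px, flash at frame %d\n",
    d[1], d[2], d[3], d[3] * x$dt_s, 1 / x$dt_s, x$pixel_um * 1000, x$flash_frame))
  invisible(x)
}

#' Read a TIFF stack as a calibrated movie
#'
#' Reads a single- or multi-page grayscale TIFF (8- or 16-bit, including
#' OME-TIFF saved as plain pages) in acquisition order. Calibration is always
#' taken from the explicit arguments; metadata embedded in the file is not
#' consulted, so argument values win by construction.
#'
#' @param path Path to the TIFF file.
#' @inheritParams ca_movie
#' @return A [ca_movie()] object. Integer sample values are returned as
#'   stored (0..255 or 0..65535), so a write/read cycle is the identity on
#'   16-bit stacks.
#' @export
read_movie <- function(path, dt_s, pixel_um, flash_frame, background_roi = NULL) {
  if (!file.exists(path)) stop("cannot read movie: no such file: ", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) stop("failed to read TIFF '", path, "': ",
                             conditionMessage(e))
  )
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop("movie '", path, "' has ", length(pages), " frame(s); need >= 2")
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("movie '", path, "' is not single-channel grayscale")
  d <- dim(pages[[1]])
  frames <- array(0, dim = c(d[1], d[2], length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
  ca_movie(frames, dt_s = dt_s, pixel_um = pixel_um,
           flash_frame = flash_frame, background_roi = background_roi)
}

#' Write a movie as a 16-bit multi-page TIFF
#'
#' Intensities are rounded to integers and clipped to the 16-bit range
#' 0..65535 before writing, so integer-valued stacks round-trip exactly
#' through [read_movie()].
#'
#' @param movie A [ca_movie()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "ca_movie"))
  d <- dim(movie$frames)
  pages <- vector("list", d[3])
  for (i in seq_len(d[3])) {
    f <- round(movie$frames[, , i])
    f[f < 0] <- 0
    f[f > 65535] <- 65535
    pages[[i]] <- f / 65535
  }
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L),
                 error = function(e) stop("failed to write TIFF '", path,
                                          "': ", conditionMessage(e)))
  invisible(path)
}

#' Subtract extracellular background fluorescence
#'
#' For each frame, the mean intensity over the movie's `background_roi` (a
#' region outside the cell) is subtracted from every pixel of that frame.
#' Negative results are clipped to 0, since camera units are non-negative and
#' downstream F/F0 ratios must not change sign. Before clipping, the mean
#' over the background ROI of each corrected frame is exactly 0.
#'
#' @param movie A [ca_movie()] with a `background_roi`.
#' @return A corrected [ca_movie()] sharing the input calibration; the
#'   `background_roi` is retained for provenance.
#' @export
subtract_background <- function(movie) {
  stopifnot(inherits(movie, "ca_movie"))
  roi <- movie$background_roi
  if (is.null(roi))
    stop("movie has no `background_roi`; supply one to ca_movie()/read_movie() ",
         "or skip background correction")
  rows <- roi[1]:roi[2]; cols <- roi[3]:roi[4]
  d <- dim(movie$frames)
  sub <- movie$frames[rows, cols, , drop = FALSE]
  bg <- colMeans(matrix(sub, nrow = length(rows) * length(cols), ncol = d[3]))
  out <- movie$frames - rep(bg, each = d[1] * d[2])
  out[out < 0] <- 0
  movie$frames <- out
  movie
}

# pixel-centre physical coordinate of a 1-based column/row index
px_center_um <- function(idx, pixel_um) (idx - 0.5) * pixel_um

# nearest 1-based pixel index for a physical coordinate
um_to_px <- function(um, pixel_um) as.integer(round(um / pixel_um + 0.5))
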