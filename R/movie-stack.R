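#' Movie stack container
#'
#' A `MovieStack` holds a time-lapse fluorescence movie as a 3-D numeric
#' array indexed `[row, col, frame]`, together with its physical calibration
#' (microns per pixel, seconds per frame) and an append-only provenance log
#' of the operations applied to it.
#'
#' @param data numeric 3-D array `[row, col, frame]` (a matrix is promoted to
#'   a single-frame stack); all values must be finite and non-negative.
#' @param pixel_size_um spatial calibration, microns per pixel (> 0).
#'   Default 0.689, the native calibration of the confocal acquisitions this
#'   pipeline was designed for.
#' @param frame_interval_s temporal calibration, seconds per frame (> 0).
#'   Default 0.625.
#' @param provenance list of previously applied operations; normally left
#'   empty and grown by the preprocessing functions.
#' @return an object of class `MovieStack`.
#' @export
movie_stack <- function(data, pixel_size_um = 0.689, frame_interval_s = 0.625,
                        provenance = list()) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a [row, col, frame] array")
  }
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data))) stop("intensities must be finite")
  if (any(data < 0)) stop("intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be > 0")
  }
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0) {
    stop("`frame_interval_s` must be > 0")
  }
  structure(
    list(data = data,
         pixel_size_um = as.numeric(pixel_size_um),
         frame_interval_s = as.numeric(frame_interval_s),
         provenance = provenance),
    class = "MovieStack")
}

#' @export
print.MovieStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("MovieStack: %d x %d px, %d frames (%.3f um/px, %.4g s/frame)\n",
              d[1], d[2], d[3], x$pixel_size_um, x$frame_interval_s))
  if (length(x$provenance)) {
    ops <- vapply(x$provenance, function(p) p$op, character(1))
    cat("  provenance:", paste(ops, collapse = " -> "), "\n")
  }
  invisible(x)
}

n_frames <- function(movie) dim(movie$data)[3]

add_provenance <- function(movie, op, params) {
  movie$provenance <- c(movie$provenance, list(c(list(op = op), params)))
  movie
}

#' Write a movie stack as a multislice TIFF
#'
#' One 16-bit unsigned page per frame. Intensities must lie in
#' `[0, 65535]`; integer-valued stacks round-trip exactly through
#' [read_movie()]. Calibration and provenance are written to a JSON sidecar
#' `<path>.json` so they survive the format.
#'
#' @param movie a `MovieStack`.
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "MovieStack"))
  if (max(movie$data) > 65535) stop("intensities exceed the 16-bit range")
  pages <- lapply(seq_len(n_frames(movie)),
                  function(f) movie$data[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(pixel_size_um = movie$pixel_size_um,
               frame_interval_s = movie$frame_interval_s,
               provenance = movie$provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multislice TIFF into a MovieStack
#'
#' Frames are taken in file order. Calibration is taken from the arguments
#' if supplied, else from a `<path>.json` sidecar written by [write_movie()],
#' else the defaults 0.689 um/px and 0.625 s/frame are attached.
#'
#' @param path path to a multislice TIFF.
#' @param pixel_size_um,frame_interval_s optional calibration overrides.
#' @return a `MovieStack`.
#' @export
read_movie <- function(path, pixel_size_um = NULL, frame_interval_s = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  ref <- dims[[1]]
  for (i in seq_along(dims)) {
    if (is.null(dims[[i]]) || length(dims[[i]]) != 2L ||
        !identical(dims[[i]], ref)) {
      stop(sprintf("page %d has incompatible geometry", i))
    }
  }
  data <- array(0, dim = c(ref[1], ref[2], length(pages)))
  for (i in seq_along(pages)) data[, , i] <- pages[[i]]
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  px <- pixel_size_um %||% meta$pixel_size_um %||% 0.689
  dt <- frame_interval_s %||% meta$frame_interval_s %||% 0.625
  movie_stack(data, pixel_size_um = as.numeric(px),
              frame_interval_s = as.numeric(dt))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
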