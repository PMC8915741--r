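#' Pixel binning
#'
#' Averages non-overlapping `bin_size x bin_size` pixel blocks within each
#' frame to reduce spatial noise before the quiescence model is estimated.
#' The frame is first cropped to the largest multiple of `bin_size`
#' (512 x 512 at the default 10 px bin becomes 51 x 51 bins) and the
#' spatial calibration is scaled accordingly.
#'
#' @param movie a `MovieStack`.
#' @param bin_size bin edge length in pixels (default 10).
#' @return a `BinnedMovie`: list with `data` (`[bin_row, bin_col, frame]`),
#'   `bin_size_px`, `effective_pixel_size_um`, `bin_area_um2`,
#'   `frame_interval_s`.
#' @export
bin_pixels <- function(movie, bin_size = 10L) {
  stopifnot(inherits(movie, "MovieStack"))
  bin_size <- as.integer(bin_size)
  if (bin_size < 1L) stop("`bin_size` must be >= 1")
  d <- dim(movie$data)
  if (bin_size > min(d[1], d[2])) stop("`bin_size` exceeds the frame size")
  nbr <- d[1] %/% bin_size
  nbc <- d[2] %/% bin_size
  eff <- bin_size * movie$pixel_size_um
  if (bin_size == 1L) {
    data <- movie$data
  } else {
    data <- array(0, dim = c(nbr, nbc, d[3]))
    hr <- nbr * bin_size
    hc <- nbc * bin_size
    for (f in seq_len(d[3])) {
      m <- movie$data[seq_len(hr), seq_len(hc), f]
      dim(m) <- c(bin_size, nbr, bin_size, nbc)
      data[, , f] <- apply(m, c(2, 4), sum) / bin_size^2
    }
  }
  structure(
    list(data = data,
         bin_size_px = bin_size,
         effective_pixel_size_um = eff,
         bin_area_um2 = eff^2,
         frame_interval_s = movie$frame_interval_s),
    class = "BinnedMovie")
}

#' Per-pixel quiescence noise model
#'
#' Estimates, at every binned pixel, the noise statistics of the periods in
#' which the cell under that pixel is not active:
#'
#' 1. the dimmest `quiescence_fraction` of that pixel's time samples (ties
#'    at the boundary value included) give a conservative noise floor: their
#'    mean `AVGmin` and standard deviation `SDqmin`;
#' 2. quiescent periods are the frames with intensity below
#'    `AVGmin + sd_multiplier * SDqmin` (the multiplier anchored at the
#'    dim-sample mean; `anchor = "none"` compares raw intensity against
#'    `sd_multiplier * SDqmin` instead);
#' 3. the mean `AVGq` and standard deviation `SDq` are recomputed within the
#'    quiescent periods.
#'
#' Pixels whose dim samples are constant (`SDqmin = 0`), whose quiescent set
#' has fewer than 2 frames, or whose `SDq` is 0 are flagged invalid and are
#' excluded from all downstream maps.
#'
#' @param binned a `BinnedMovie` with at least 10 frames.
#' @param quiescence_fraction fraction of the recording assumed quiescent at
#'   every pixel, in (0, 1] (default 0.20).
#' @param sd_multiplier quiescence cut in units of `SDqmin` (default 11.0).
#' @param anchor `"avgmin"` (default) or `"none"`; see above.
#' @return a `QuiescenceModel`: matrices `avg_q`, `sd_q`, `avg_min`,
#'   `sd_qmin`, logical matrix `valid`, logical array `quiescent_mask`
#'   (`[bin_row, bin_col, frame]`), and the parameters used.
#' @export
estimate_quiescence <- function(binned, quiescence_fraction = 0.20,
                                sd_multiplier = 11.0,
                                anchor = c("avgmin", "none")) {
  stopifnot(inherits(binned, "BinnedMovie"))
  anchor <- match.arg(anchor)
  if (quiescence_fraction <= 0 || quiescence_fraction > 1) {
    stop("`quiescence_fraction` must be in (0, 1]")
  }
  d <- dim(binned$data)
  nf <- d[3]
  if (nf < 10L) stop("need at least 10 frames to estimate quiescence")
  np <- d[1] * d[2]
  x <- binned$data
  dim(x) <- c(np, nf)

  n_dim <- max(1L, ceiling(quiescence_fraction * nf))
  sorted <- apply(x, 1, sort)          # nf x np
  boundary <- sorted[n_dim, ]

  dim_mask <- sweep(x, 1, boundary, "<=")   # boundary ties included
  n_d <- rowSums(dim_mask)
  s1 <- rowSums(x * dim_mask)
  s2 <- rowSums(x * x * dim_mask)
  avg_min <- s1 / n_d
  var_min <- pmax(0, (s2 - n_d * avg_min^2) / pmax(1, n_d - 1))
  sd_qmin <- ifelse(n_d > 1, sqrt(var_min), 0)

  cut <- if (anchor == "avgmin") avg_min + sd_multiplier * sd_qmin
         else sd_multiplier * sd_qmin
  qmask <- sweep(x, 1, cut, "<")
  n_q <- rowSums(qmask)
  q1 <- rowSums(x * qmask)
  q2 <- rowSums(x * x * qmask)
  avg_q <- ifelse(n_q > 0, q1 / n_q, NA_real_)
  var_q <- pmax(0, (q2 - n_q * avg_q^2) / pmax(1, n_q - 1))
  sd_q <- ifelse(n_q > 1, sqrt(var_q), 0)

  valid <- sd_qmin > 0 & n_q >= 2 & !is.na(sd_q) & sd_q > 0
  avg_q[!valid] <- NA_real_
  sd_q[!valid] <- NA_real_

  shape2 <- function(v) { dim(v) <- c(d[1], d[2]); v }
  qm <- qmask
  dim(qm) <- d
  structure(
    list(avg_q = shape2(avg_q), sd_q = shape2(sd_q),
         avg_min = shape2(avg_min), sd_qmin = shape2(sd_qmin),
         valid = shape2(valid), quiescent_mask = qm,
         n_invalid = sum(!valid),
         params = list(quiescence_fraction = quiescence_fraction,
                       sd_multiplier = sd_multiplier, anchor = anchor),
         dim = d),
    class = "QuiescenceModel")
}

#' @export
print.QuiescenceModel <- function(x, ...) {
  cat(sprintf(
    "QuiescenceModel: %d x %d bins, %d frames; %d invalid pixel(s)\n",
    x$dim[1], x$dim[2], x$dim[3], x$n_invalid))
  cat(sprintf("  quiescence_fraction = %.2f, sd_multiplier = %.1f, anchor = %s\n",
              x$params$quiescence_fraction, x$params$sd_multiplier,
              x$params$anchor))
  invisible(x)
}

#' Convert a binned movie to Z-scores
#'
#' `Z[f, p] = (I[f, p] - AVGq[p]) / SDq[p]` at every valid pixel; invalid
#' pixels are set to `NA` and excluded from all downstream detection.
#' By construction the Z-scores of a pixel's quiescent samples have mean 0
#' and standard deviation 1 exactly, so a fixed Z threshold has the same
#' meaning for dim and bright cells.
#'
#' @param binned the `BinnedMovie` the model was estimated from.
#' @param model the matching `QuiescenceModel`.
#' @return a `ZScoreMovie`: list with `data` (`[bin_row, bin_col, frame]`
#'   Z-scores), `bin_area_um2`, `frame_interval_s`, `valid`, and the model's
#'   `quiescent_mask`.
#' @export
zscore <- function(binned, model) {
  stopifnot(inherits(binned, "BinnedMovie"), inherits(model, "QuiescenceModel"))
  if (!identical(dim(binned$data), model$dim)) {
    stop("movie and quiescence model geometries differ")
  }
  d <- model$dim
  z <- array(NA_real_, dim = d)
  for (f in seq_len(d[3])) {
    z[, , f] <- (binned$data[, , f] - model$avg_q) / model$sd_q
  }
  structure(
    list(data = z,
         bin_area_um2 = binned$bin_area_um2,
         frame_interval_s = binned$frame_interval_s,
         valid = model$valid,
         quiescent_mask = model$quiescent_mask),
    class = "ZScoreMovie")
}
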