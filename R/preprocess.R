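#' @title Preprocessing chain for fluorescence movies
#' @description Rigid motion stabilization, photobleaching correction,
#'   temporal box averaging and spatial Gaussian smoothing, in the order a
#'   recording is normally conditioned before noise modelling:
#'   stabilize -> debleach -> temporal -> spatial. Every step preserves frame
#'   count, frame shape and calibration, and appends itself to the movie's
#'   provenance log.
#' @name preprocess
NULL

# mirror an out-of-range index back into 1..n (symmetric reflection,
# edge duplicated: 0 -> 1, -1 -> 2, n+1 -> n, ...)
reflect_index <- function(i, n) {
  i <- ifelse(i < 1L, 1L - i, i)
  i <- ifelse(i > n, 2L * n + 1L - i, i)
  i
}

# translate a matrix by (dr, dc) integer pixels, filling vacated pixels
shift_matrix <- function(m, dr, dc, fill) {
  out <- matrix(fill, nrow(m), ncol(m))
  r_src <- seq_len(nrow(m)) - dr
  c_src <- seq_len(ncol(m)) - dc
  rk <- r_src >= 1 & r_src <= nrow(m)
  ck <- c_src >= 1 & c_src <= ncol(m)
  out[rk, ck] <- m[r_src[rk], c_src[ck]]
  out
}

# normalized cross-correlation between the overlapping regions of `ref`
# and `fr` translated by (dr, dc)
overlap_ncc <- function(ref, fr, dr, dc) {
  nr <- nrow(ref); nc <- ncol(ref)
  r1 <- max(1L, 1L + dr); r2 <- min(nr, nr + dr)
  c1 <- max(1L, 1L + dc); c2 <- min(nc, nc + dc)
  if (r1 > r2 || c1 > c2) return(-Inf)
  a <- ref[r1:r2, c1:c2]
  b <- fr[(r1:r2) - dr, (c1:c2) - dc]
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a * a) * sum(b * b))
  if (den == 0) return(0)
  sum(a * b) / den
}

#' Rigid motion stabilization
#'
#' Each frame is translated by the integer pixel shift that maximizes its
#' normalized cross-correlation with the first frame. Estimated shifts are
#' logged in the provenance. A frame whose best shift lands on the edge of
#' the search window (i.e. exceeds `max_shift_px`) is left untranslated with
#' a warning.
#'
#' @param movie a `MovieStack` with at least 2 frames.
#' @param max_shift_px search radius in pixels (default 5).
#' @return the stabilized `MovieStack`.
#' @export
stabilize <- function(movie, max_shift_px = 5L) {
  stopifnot(inherits(movie, "MovieStack"))
  nf <- n_frames(movie)
  if (nf < 2L) stop("stabilization needs at least 2 frames")
  max_shift_px <- as.integer(max_shift_px)
  ref <- movie$data[, , 1]
  span <- seq.int(-max_shift_px - 1L, max_shift_px + 1L)
  shifts <- matrix(0L, nf, 2L)
  for (f in 2:nf) {
    fr <- movie$data[, , f]
    best <- c(0L, 0L); best_s <- -Inf
    for (dr in span) for (dc in span) {
      s <- overlap_ncc(ref, fr, dr, dc)
      if (s > best_s) { best_s <- s; best <- c(dr, dc) }
    }
    if (max(abs(best)) > max_shift_px) {
      warning(sprintf("frame %d: estimated shift exceeds max_shift_px; left in place", f))
      best <- c(0L, 0L)
    }
    shifts[f, ] <- best
    if (any(best != 0L)) {
      movie$data[, , f] <- shift_matrix(fr, best[1], best[2],
                                        fill = stats::median(fr))
    }
  }
  add_provenance(movie, "stabilize",
                 list(max_shift_px = max_shift_px, shifts = shifts))
}

#' Photobleaching correction
#'
#' Removes the slow decay of whole-frame brightness. The `"exponential"`
#' model fits \eqn{m_t = a e^{-t/\tau}} to the frame means (least squares on
#' the log scale) and divides each frame by the fitted relative decay; if the
#' fit fails or finds no decay it falls back to `"frame-mean"` normalization,
#' which rescales every frame to the first frame's mean exactly.
#'
#' @param movie a `MovieStack`; all frame means must be positive.
#' @param model `"exponential"` (default) or `"frame-mean"`.
#' @return the corrected `MovieStack`.
#' @export
debleach <- function(movie, model = c("exponential", "frame-mean")) {
  stopifnot(inherits(movie, "MovieStack"))
  model <- match.arg(model)
  nf <- n_frames(movie)
  m <- apply(movie$data, 3, mean)
  if (any(m == 0)) stop("a frame has zero mean intensity; cannot debleach")
  used <- model
  pars <- list()
  if (model == "exponential") {
    t <- seq_len(nf) - 1
    fit <- try(stats::lm(log(m) ~ t), silent = TRUE)
    slope <- if (inherits(fit, "try-error")) NA_real_ else stats::coef(fit)[2]
    if (is.na(slope) || slope >= 0) {
      used <- "frame-mean"
    } else {
      pred <- exp(stats::fitted(fit))
      factor <- pred[1] / pred
      pars <- list(tau_frames = -1 / slope)
    }
  }
  if (used == "frame-mean") factor <- m[1] / m
  for (f in seq_len(nf)) movie$data[, , f] <- movie$data[, , f] * factor[f]
  add_provenance(movie, "debleach", c(list(model = used), pars))
}

#' Temporal box averaging
#'
#' Replaces each frame by the mean of a `(2*halfwidth + 1)`-frame window
#' centred on it; windows are truncated at the ends of the recording so the
#' frame count is unchanged. With the default `halfwidth = 2` at
#' 0.625 s/frame the window spans 3.13 s, which is recorded in the
#' provenance as `window_s`.
#'
#' @param movie a `MovieStack` with at least `2*halfwidth + 1` frames.
#' @param halfwidth non-negative integer (default 2).
#' @return the averaged `MovieStack`.
#' @export
temporal_average <- function(movie, halfwidth = 2L) {
  stopifnot(inherits(movie, "MovieStack"))
  halfwidth <- as.integer(halfwidth)
  if (halfwidth < 0L) stop("`halfwidth` must be >= 0")
  nf <- n_frames(movie)
  if (nf < 2L * halfwidth + 1L) stop("too few frames for this window")
  window_s <- (2 * halfwidth + 1) * movie$frame_interval_s
  if (halfwidth > 0L) {
    d <- dim(movie$data)
    x <- movie$data
    dim(x) <- c(d[1] * d[2], d[3])
    cs <- x
    for (f in 2:nf) cs[, f] <- cs[, f - 1L] + x[, f]
    lo <- pmax(seq_len(nf) - halfwidth, 1L)
    hi <- pmin(seq_len(nf) + halfwidth, nf)
    out <- x
    for (f in seq_len(nf)) {
      s <- cs[, hi[f]] - (if (lo[f] > 1L) cs[, lo[f] - 1L] else 0)
      out[, f] <- s / (hi[f] - lo[f] + 1L)
    }
    dim(out) <- d
    movie$data <- out
  }
  add_provenance(movie, "temporal_average",
                 list(halfwidth = halfwidth, window_s = window_s))
}

# normalized 1-D Gaussian tap weights; the 2-D kernel is their outer product
gaussian_taps <- function(kernel, sd) {
  half <- (kernel - 1L) %/% 2L
  g <- exp(-(seq.int(-half, half))^2 / (2 * sd^2))
  g / sum(g)
}

smooth_frame <- function(m, taps) {
  half <- (length(taps) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  tmp <- matrix(0, nr, nc)
  for (k in seq_along(taps)) {
    idx <- reflect_index(seq_len(nr) + (k - 1L - half), nr)
    tmp <- tmp + taps[k] * m[idx, , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (k in seq_along(taps)) {
    idx <- reflect_index(seq_len(nc) + (k - 1L - half), nc)
    out <- out + taps[k] * tmp[, idx, drop = FALSE]
  }
  out
}

#' Spatial Gaussian smoothing
#'
#' Convolves every frame with a normalized discrete `kernel x kernel`
#' Gaussian of the given standard deviation (default 5 x 5, sd = 1.0 px).
#' Borders are handled by symmetric reflection, so frame shape is preserved
#' and the operation is non-expansive.
#'
#' @param movie a `MovieStack`.
#' @param kernel odd kernel width in pixels, at most the smaller frame side.
#' @param sd Gaussian standard deviation in pixels (> 0).
#' @return the smoothed `MovieStack`.
#' @export
spatial_smooth <- function(movie, kernel = 5L, sd = 1.0) {
  stopifnot(inherits(movie, "MovieStack"))
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L) stop("`kernel` must be odd and >= 1")
  d <- dim(movie$data)
  if (kernel > min(d[1], d[2])) stop("`kernel` exceeds the frame size")
  if (sd <= 0) stop("`sd` must be > 0")
  taps <- gaussian_taps(kernel, sd)
  for (f in seq_len(d[3])) {
    movie$data[, , f] <- smooth_frame(movie$data[, , f], taps)
  }
  add_provenance(movie, "spatial_smooth", list(kernel = kernel, sd = sd))
}

#' Replay a logged preprocessing chain
#'
#' Re-applies the operations recorded in a provenance log to a raw movie,
#' reproducing the preprocessed output bit for bit.
#'
#' @param movie the raw `MovieStack`.
#' @param provenance a provenance list from a preprocessed movie.
#' @return the reprocessed `MovieStack`.
#' @export
apply_chain <- function(movie, provenance) {
  for (p in provenance) {
    movie <- switch(p$op,
      stabilize = stabilize(movie, max_shift_px = p$max_shift_px),
      debleach = debleach(movie, model = p$model),
      temporal_average = temporal_average(movie, halfwidth = p$halfwidth),
      spatial_smooth = spatial_smooth(movie, kernel = p$kernel, sd = p$sd),
      stop(sprintf("unknown operation '%s' in provenance", p$op)))
  }
  movie
}
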