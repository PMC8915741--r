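#' Parameters for the synthetic urothelial movie generator
#'
#' The generator emulates a dye-loaded urothelial sheet: ovoid cells
#' (random non-overlapping ellipses, axes 10-30 um) with per-cell
#' log-normal baseline brightness on a dim background (uneven dye loading),
#' optional exponential photobleaching and rigid drift, and additive
#' Gaussian noise whose standard deviation scales as
#' `noise_sd * sqrt(intensity / noise_ref)` (a shot-noise surrogate).
#' Injected Ca2+ events raise the intensity over a contiguous footprint by
#' `amplitude` multiples of the local quiescent noise SD, with a 1-frame
#' linear rise and a 2-frame linear decay inside the stated duration.
#'
#' @param n_frames number of frames (default 500).
#' @param height,width frame size in pixels (default 510 x 510, an exact
#'   multiple of the 10 px analysis bin).
#' @param pixel_size_um,frame_interval_s calibration (defaults 0.689 um/px,
#'   0.625 s/frame).
#' @param n_cells number of cells to place (default 80).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of per-cell
#'   baseline brightness, in intensity counts (defaults log(2000), 0.4).
#' @param background background intensity outside cells (default 100).
#' @param noise_sd noise SD at the reference intensity (default 50 counts).
#' @param noise_ref reference intensity for the noise scaling (default
#'   2000 counts).
#' @param bleach_tau_s exponential bleaching time constant in seconds, or
#'   `NULL` (default) for no bleaching.
#' @param drift_px_per_frame rigid drift per frame, a length-2 numeric
#'   (rows, cols); cumulative drift is rounded to integer pixels.
#'   Default `c(0, 0)`.
#' @param events either an [event_plan()] describing events to place
#'   automatically, or an explicit list of events, each a list with
#'   `footprint` (integer matrix of `(row, col)` pixels), `onset_frame`,
#'   `duration_frames`, `amplitude`; default none.
#' @param seed integer seed driving all randomness (default 1).
#' @return a validated parameter list of class `movie_params`.
#' @export
movie_params <- function(n_frames = 500L, height = 510L, width = 510L,
                         pixel_size_um = 0.689, frame_interval_s = 0.625,
                         n_cells = 80L,
                         baseline_meanlog = log(2000), baseline_sdlog = 0.4,
                         background = 100, noise_sd = 50, noise_ref = 2000,
                         bleach_tau_s = NULL, drift_px_per_frame = c(0, 0),
                         events = list(), seed = 1L) {
  if (length(drift_px_per_frame) == 1L) {
    drift_px_per_frame <- rep(drift_px_per_frame, 2L)
  }
  p <- list(n_frames = as.integer(n_frames), height = as.integer(height),
            width = as.integer(width), pixel_size_um = pixel_size_um,
            frame_interval_s = frame_interval_s, n_cells = as.integer(n_cells),
            baseline_meanlog = baseline_meanlog,
            baseline_sdlog = baseline_sdlog, background = background,
            noise_sd = noise_sd, noise_ref = noise_ref,
            bleach_tau_s = bleach_tau_s,
            drift_px_per_frame = drift_px_per_frame,
            events = events, seed = as.integer(seed))
  with(p, {
    stopifnot(n_frames >= 1, height >= 1, width >= 1, pixel_size_um > 0,
              frame_interval_s > 0, n_cells >= 0, background > 0,
              noise_sd > 0, noise_ref > 0)
  })
  if (!is.null(p$bleach_tau_s) && p$bleach_tau_s <= 0) {
    stop("`bleach_tau_s` must be > 0 or NULL")
  }
  class(p) <- "movie_params"
  p
}

#' Plan a set of injected Ca2+ events
#'
#' Describes `n` events to be placed automatically by [generate_movie()]:
#' footprints are the `footprint_px` pixels of a host cell nearest its
#' centre (cells large enough to host are required), host-cell centroids
#' are kept at least `min_sep_px` apart so events stay spatially distinct,
#' and onsets are drawn uniformly over the usable frame range.
#'
#' @param n number of events (default 20).
#' @param amplitude event amplitude as a multiple of the local per-pixel
#'   quiescent noise SD (default 8).
#' @param duration_frames total event support in frames, rise and decay
#'   included (default 8).
#' @param footprint_px footprint size in original pixels (default 800,
#'   i.e. 8 bins at the default 10 px binning).
#' @param min_sep_px minimum distance between host-cell centroids
#'   (default 80 px).
#' @param margin_frames onset kept at least this far from both ends of the
#'   recording (default 12).
#' @return an object of class `event_plan`.
#' @export
event_plan <- function(n = 20L, amplitude = 8, duration_frames = 8L,
                       footprint_px = 800L, min_sep_px = 80,
                       margin_frames = 12L) {
  stopifnot(n >= 0, amplitude > 0, duration_frames >= 1, footprint_px >= 1)
  structure(list(n = as.integer(n), amplitude = amplitude,
                 duration_frames = as.integer(duration_frames),
                 footprint_px = as.integer(footprint_px),
                 min_sep_px = min_sep_px,
                 margin_frames = as.integer(margin_frames)),
            class = "event_plan")
}

# amplitude weight per frame of the event support: 1-frame linear rise,
# plateau, 2-frame linear decay, all inside `dur` frames
event_weights <- function(dur) {
  if (dur == 1L) return(1)
  if (dur == 2L) return(c(1, 0.5))
  if (dur == 3L) return(c(1, 2 / 3, 1 / 3))
  c(0.5, rep(1, dur - 3L), 2 / 3, 1 / 3)
}

# rasterize one ellipse into a vector of pixel indices
ellipse_mask <- function(height, width, cy, cx, a, b, th) {
  r <- ceiling(max(a, b))
  ry <- max(1, floor(cy - r)):min(height, ceiling(cy + r))
  rx <- max(1, floor(cx - r)):min(width, ceiling(cx + r))
  yy <- outer(ry - cy, rep(1, length(rx)))
  xx <- outer(rep(1, length(ry)), rx - cx)
  u <- yy * cos(th) + xx * sin(th)
  v <- -yy * sin(th) + xx * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  as.integer(outer(ry, (rx - 1L) * height, "+")[inside])
}

# sample non-overlapping ellipses (axes 10-30 um). When `hosts` is given,
# that many cells large enough to hold `host_area_px` pixels and with
# centroids at least `host_sep_px` apart are placed first, so planned
# events always have somewhere to live; the remaining cells fill in
# around them.
place_cells <- function(height, width, n_cells, pixel_size_um,
                        hosts = 0L, host_area_px = 0L, host_sep_px = 0) {
  semi_min_px <- 5 / pixel_size_um    # 10 um axis = 5 um semi-axis
  semi_max_px <- 15 / pixel_size_um   # 30 um axis
  for (attempt in seq_len(30L)) {
    centers <- matrix(0, 0, 2)
    axes <- matrix(0, 0, 2)
    theta <- numeric(0)
    n_placed_hosts <- 0L
    tries <- 0L
    max_tries <- 400L * max(n_cells, 1L)
    while (nrow(centers) < n_cells && tries < max_tries) {
      tries <- tries + 1L
      as_host <- n_placed_hosts < hosts
      a <- stats::runif(1, semi_min_px, semi_max_px)
      b <- stats::runif(1, semi_min_px, semi_max_px)
      if (as_host && (pi * a * b < 1.15 * host_area_px ||
                      pi * a * b > max(2.5 * 1.15 * host_area_px,
                                       pi * semi_min_px^2 * 4))) next
      r <- max(a, b)
      if (1 + r >= height - r || 1 + r >= width - r) next
      cy <- stats::runif(1, 1 + r, height - r)
      cx <- stats::runif(1, 1 + r, width - r)
      if (nrow(centers)) {
        d <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
        if (any(d < r + pmax(axes[, 1], axes[, 2]))) next
        if (as_host && n_placed_hosts > 0L &&
            any(d[seq_len(n_placed_hosts)] < host_sep_px)) next
      }
      centers <- rbind(centers, c(cy, cx))
      axes <- rbind(axes, c(a, b))
      theta <- c(theta, stats::runif(1, 0, pi))
      if (as_host) n_placed_hosts <- n_placed_hosts + 1L
    }
    if (n_placed_hosts >= hosts) break
  }
  if (n_placed_hosts < hosts) {
    stop("could not place the requested event host cells")
  }
  n <- nrow(centers)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    masks[[i]] <- ellipse_mask(height, width, centers[i, 1], centers[i, 2],
                               axes[i, 1], axes[i, 2], theta[i])
  }
  list(masks = masks, centers = centers, n = n, n_hosts = n_placed_hosts)
}

# footprint of an event in cell i: the footprint_px pixels nearest the
# cell centroid
cell_footprint <- function(cells, i, footprint_px, height) {
  idx <- cells$masks[[i]]
  if (length(idx) < footprint_px) {
    stop("host cell smaller than the requested footprint")
  }
  r <- (idx - 1L) %% height + 1L
  c <- (idx - 1L) %/% height + 1L
  d2 <- (r - cells$centers[i, 1])^2 + (c - cells$centers[i, 2])^2
  keep <- order(d2)[seq_len(footprint_px)]
  cbind(row = r[keep], col = c[keep])
}

#' Generate a synthetic urothelial-sheet movie with known ground truth
#'
#' Renders the scene described by [movie_params()] and returns both the
#' noisy 16-bit movie and the exact ground truth of every injected event.
#' The same parameters and seed always produce bit-identical output.
#'
#' @param params a [movie_params()] object.
#' @param keep_signal if `TRUE`, also return the noise-free signal array
#'   (useful as a reference for recovery assessments); default `FALSE`.
#' @return a list with `movie` (a `MovieStack`, intensities quantized to
#'   integer counts), `truth` (data frame: `event_id`, `cell_id`,
#'   `onset_frame`, `duration_frames`, `amplitude`, `n_px`,
#'   `centroid_row`, `centroid_col`), `footprints` (list of pixel
#'   matrices), `params`, and optionally `signal`.
#' @export
generate_movie <- function(params, keep_signal = FALSE) {
  stopifnot(inherits(params, "movie_params"))
  p <- params
  set.seed(p$seed)
  h <- p$height; w <- p$width; nf <- p$n_frames

  plan <- if (inherits(p$events, "event_plan")) p$events else NULL
  cells <- place_cells(h, w, p$n_cells, p$pixel_size_um,
                       hosts = if (is.null(plan)) 0L else plan$n,
                       host_area_px = if (is.null(plan)) 0L else plan$footprint_px,
                       host_sep_px = if (is.null(plan)) 0 else plan$min_sep_px)
  if (cells$n < p$n_cells) {
    warning(sprintf("placed %d of %d requested cells", cells$n, p$n_cells))
  }
  brightness <- stats::rlnorm(cells$n, p$baseline_meanlog, p$baseline_sdlog)
  baseline <- matrix(p$background, h, w)
  for (i in seq_len(cells$n)) {
    baseline[cells$masks[[i]]] <- baseline[cells$masks[[i]]] + brightness[i]
  }

  # resolve the event list
  if (!is.null(plan)) {
    lo <- 1L + plan$margin_frames
    hi <- nf - plan$duration_frames - plan$margin_frames + 1L
    if (hi < lo) stop("recording too short for the planned events")
    onsets <- lo + sample.int(hi - lo + 1L, plan$n, replace = TRUE) - 1L
    events <- lapply(seq_len(plan$n), function(i) {
      list(cell_id = i,
           footprint = cell_footprint(cells, i, plan$footprint_px, h),
           onset_frame = onsets[i], duration_frames = plan$duration_frames,
           amplitude = plan$amplitude)
    })
  } else {
    events <- p$events
  }

  # validate events and reject ambiguous overlaps
  occupied <- list()
  for (k in seq_along(events)) {
    e <- events[[k]]
    fp <- e$footprint
    if (is.null(fp) || !is.matrix(fp) || !nrow(fp)) {
      stop(sprintf("event %d: footprint must be a non-empty (row, col) matrix", k))
    }
    if (any(fp[, 1] < 1 | fp[, 1] > h | fp[, 2] < 1 | fp[, 2] > w)) {
      stop(sprintf("event %d: footprint outside the %d x %d frame", k, h, w))
    }
    if (e$duration_frames < 1L) stop(sprintf("event %d: duration < 1 frame", k))
    if (e$amplitude <= 0) stop(sprintf("event %d: amplitude must be > 0", k))
    if (e$onset_frame < 1L || e$onset_frame + e$duration_frames - 1L > nf) {
      stop(sprintf("event %d: frames outside the recording", k))
    }
    idx <- fp[, 1] + (fp[, 2] - 1L) * h
    span <- c(e$onset_frame, e$onset_frame + e$duration_frames - 1L)
    for (o in occupied) {
      if (span[1] <= o$span[2] && span[2] >= o$span[1] &&
          length(intersect(idx, o$idx))) {
        stop(sprintf("event %d overlaps event %d on the same pixels; rejected",
                     k, o$k))
      }
    }
    occupied[[length(occupied) + 1L]] <- list(k = k, idx = idx, span = span)
  }

  # per-pixel local noise SD at baseline, used to scale event amplitudes
  local_sd <- p$noise_sd * sqrt(baseline / p$noise_ref)

  bleach <- if (is.null(p$bleach_tau_s)) rep(1, nf) else
    exp(-(seq_len(nf) - 1L) * p$frame_interval_s / p$bleach_tau_s)

  # additive event signal per frame (sparse: only touched pixels stored)
  ev_add <- vector("list", nf)
  for (k in seq_along(events)) {
    e <- events[[k]]
    idx <- e$footprint[, 1] + (e$footprint[, 2] - 1L) * h
    wts <- event_weights(e$duration_frames)
    for (j in seq_len(e$duration_frames)) {
      f <- e$onset_frame + j - 1L
      ev_add[[f]] <- rbind(ev_add[[f]],
                           cbind(idx, e$amplitude * wts[j] * local_sd[idx]))
    }
  }

  drift <- round(outer(seq_len(nf) - 1L, p$drift_px_per_frame))
  has_drift <- any(drift != 0)

  data <- array(0, dim = c(h, w, nf))
  signal <- if (keep_signal) array(0, dim = c(h, w, nf)) else NULL
  for (f in seq_len(nf)) {
    s <- baseline
    if (!is.null(ev_add[[f]])) {
      s[ev_add[[f]][, 1]] <- s[ev_add[[f]][, 1]] + ev_add[[f]][, 2]
    }
    # the event fluorophores bleach with the rest of the dye
    s <- s * bleach[f]
    if (has_drift) {
      s <- shift_matrix(s, drift[f, 1], drift[f, 2], fill = p$background)
    }
    if (keep_signal) signal[, , f] <- s
    noisy <- s + stats::rnorm(h * w) * (p$noise_sd * sqrt(s / p$noise_ref))
    data[, , f] <- pmin(pmax(round(noisy), 0), 65535)
  }

  truth <- if (length(events)) do.call(rbind, lapply(seq_along(events),
    function(k) {
      e <- events[[k]]
      data.frame(event_id = k,
                 cell_id = if (is.null(e$cell_id)) NA_integer_ else e$cell_id,
                 onset_frame = e$onset_frame,
                 duration_frames = e$duration_frames,
                 amplitude = e$amplitude,
                 n_px = nrow(e$footprint),
                 centroid_row = mean(e$footprint[, 1]),
                 centroid_col = mean(e$footprint[, 2]))
    })) else data.frame(event_id = integer(), cell_id = integer(),
                        onset_frame = integer(), duration_frames = integer(),
                        amplitude = numeric(), n_px = integer(),
                        centroid_row = numeric(), centroid_col = numeric())

  movie <- movie_stack(data, pixel_size_um = p$pixel_size_um,
                       frame_interval_s = p$frame_interval_s)
  out <- list(movie = movie, truth = truth,
              footprints = lapply(events, `[[`, "footprint"),
              params = p)
  if (keep_signal) out$signal <- signal
  out
}
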