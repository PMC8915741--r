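#' @title Ca2+ event detection and spatio-temporal tracking
#' @description Active pixels are defined by a Z-score threshold
#'   (default >= 2.7), residual noise is removed with a per-frame particle
#'   filter (connected components of <= 3 binned pixels dropped), contiguous
#'   active pixels are coalesced into per-frame particles, and particles in
#'   consecutive frames that share at least one bin are linked (transitive
#'   closure) into spatio-temporal (ST) event objects. Each object carries
#'   duration, area, peak Z, and the integrated output
#'   Zum2s = sum over member voxels of Z x bin area (um^2) x frame
#'   interval (s), which the field-of-view summary normalizes per minute.
#' @name event-detection
NULL

# connected-component labels of a logical matrix; 0 = background
label_frame_components <- function(m, connectivity = 4L) {
  nr <- nrow(m); nc <- ncol(m)
  labels <- matrix(0L, nr, nc)
  idx <- which(m)
  if (!length(idx)) return(labels)
  map <- matrix(0L, nr, nc)
  map[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  for (o in offs) {
    rn <- r + o[1]; cn <- c + o[2]
    ok <- rn >= 1L & rn <= nr & cn >= 1L & cn <= nc
    if (!any(ok)) next
    nb <- map[cbind(rn[ok], cn[ok])]
    a <- which(ok)[nb > 0L]
    b <- nb[nb > 0L]
    for (k in seq_along(a)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  labels[idx] <- match(roots, unique(roots))
  labels
}

#' Threshold Z-scores into an active-event mask
#'
#' Marks voxels with `Z >= z_threshold` active, then removes, frame by
#' frame, connected components of `min_particle_px` or fewer binned pixels
#' (the particle filter). `NA` Z-scores (invalid pixels) are never active.
#'
#' @param z a `ZScoreMovie`.
#' @param z_threshold detection threshold in Z-score units (default 2.7,
#'   inclusive).
#' @param min_particle_px components of at most this many pixels are
#'   discarded as noise (default 3).
#' @param connectivity within-frame pixel connectivity, 4 (default) or 8.
#' @return logical array `[bin_row, bin_col, frame]`.
#' @export
detect_active_mask <- function(z, z_threshold = 2.7, min_particle_px = 3L,
                               connectivity = 4L) {
  stopifnot(inherits(z, "ZScoreMovie"))
  if (z_threshold <= 0 || min_particle_px < 0) stop("thresholds must be positive")
  d <- dim(z$data)
  mask <- !is.na(z$data) & z$data >= z_threshold
  for (f in seq_len(d[3])) {
    fr <- mask[, , f]
    if (!any(fr)) next
    lab <- label_frame_components(fr, connectivity)
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes <= min_particle_px)
    if (length(drop)) {
      fr[lab %in% drop] <- FALSE
      mask[, , f] <- fr
    }
  }
  mask
}

#' Coalesce active pixels into per-frame particles
#'
#' One particle per connected component per frame, with pixel count, area
#' in um^2, and the maximum and sum of its Z-scores.
#'
#' @param mask logical array from [detect_active_mask()].
#' @param z the `ZScoreMovie` the mask came from.
#' @param connectivity within-frame pixel connectivity, 4 (default) or 8.
#' @return a list with `table` (data frame: `particle_id`, `frame`, `n_px`,
#'   `area_um2`, `max_zscr`, `sum_zscr`) and `pixels` (per particle, an
#'   integer matrix of `(bin_row, bin_col)` coordinates).
#' @export
extract_particles <- function(mask, z, connectivity = 4L) {
  stopifnot(inherits(z, "ZScoreMovie"))
  if (!identical(dim(mask), dim(z$data))) stop("mask and Z geometries differ")
  d <- dim(mask)
  rows <- list()
  pixels <- list()
  pid <- 0L
  for (f in seq_len(d[3])) {
    fr <- mask[, , f]
    if (!any(fr)) next
    lab <- label_frame_components(fr, connectivity)
    zf <- z$data[, , f]
    for (l in seq_len(max(lab))) {
      ii <- which(lab == l)
      pid <- pid + 1L
      zv <- zf[ii]
      rows[[pid]] <- data.frame(
        particle_id = pid, frame = f, n_px = length(ii),
        area_um2 = length(ii) * z$bin_area_um2,
        max_zscr = max(zv), sum_zscr = sum(zv))
      pixels[[pid]] <- cbind(row = (ii - 1L) %% d[1] + 1L,
                             col = (ii - 1L) %/% d[1] + 1L)
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(particle_id = integer(), frame = integer(), n_px = integer(),
               area_um2 = numeric(), max_zscr = numeric(),
               sum_zscr = numeric())
  list(table = table, pixels = pixels, dim = d)
}

#' Link particles into spatio-temporal event objects
#'
#' Particles in consecutive frames that share at least one binned pixel are
#' linked; the transitive closure of the links (so merging or splitting
#' blobs stay one object) forms one ST object. Objects therefore have no
#' temporal gaps. Per object: duration in s (frame span x frame interval),
#' maximum particle area, maximum Z, centroid, and the integrated output in
#' Zum2s.
#'
#' @param particles result of [extract_particles()].
#' @param z the `ZScoreMovie` the particles came from.
#' @return a list with `events` (one data frame row per ST object:
#'   `event_id`, `onset_frame`, `end_frame`, `n_frames`, `onset_s`,
#'   `duration_s`, `n_voxels`, `max_area_um2`, `max_zscr`, `sum_zscr`,
#'   `output_zum2s`, `centroid_row`, `centroid_col`) and `voxels` (per
#'   object, a data frame of member voxels `frame`, `row`, `col`).
#' @export
track_st_objects <- function(particles, z) {
  stopifnot(inherits(z, "ZScoreMovie"))
  tab <- particles$table
  np <- nrow(tab)
  empty <- data.frame(
    event_id = integer(), onset_frame = integer(), end_frame = integer(),
    n_frames = integer(), onset_s = numeric(), duration_s = numeric(),
    n_voxels = integer(), max_area_um2 = numeric(), max_zscr = numeric(),
    sum_zscr = numeric(), output_zum2s = numeric(),
    centroid_row = numeric(), centroid_col = numeric())
  if (!np) return(list(events = empty, voxels = list()))
  d <- particles$dim
  parent <- seq_len(np)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  prev_map <- NULL
  prev_frame <- -1L
  for (f in sort(unique(tab$frame))) {
    ids <- tab$particle_id[tab$frame == f]
    cur_map <- matrix(0L, d[1], d[2])
    for (id in ids) cur_map[particles$pixels[[id]]] <- id
    if (!is.null(prev_map) && f == prev_frame + 1L) {
      for (id in ids) {
        hits <- unique(prev_map[particles$pixels[[id]]])
        for (h in hits[hits > 0L]) {
          ra <- find(id); rb <- find(h)
          if (ra != rb) parent[rb] <- ra
        }
      }
    }
    prev_map <- cur_map
    prev_frame <- f
  }
  roots <- vapply(seq_len(np), find, integer(1))
  groups <- split(seq_len(np), match(roots, unique(roots)))
  dt <- z$frame_interval_s
  area <- z$bin_area_um2
  events <- vector("list", length(groups))
  voxels <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    ids <- groups[[g]]
    sub <- tab[tab$particle_id %in% ids, ]
    vx <- do.call(rbind, lapply(ids, function(id) {
      px <- particles$pixels[[id]]
      data.frame(frame = tab$frame[tab$particle_id == id],
                 row = px[, 1], col = px[, 2])
    }))
    f1 <- min(sub$frame); f2 <- max(sub$frame)
    events[[g]] <- data.frame(
      event_id = g, onset_frame = f1, end_frame = f2,
      n_frames = f2 - f1 + 1L,
      onset_s = (f1 - 1L) * dt,
      duration_s = (f2 - f1 + 1L) * dt,
      n_voxels = nrow(vx),
      max_area_um2 = max(sub$area_um2),
      max_zscr = max(sub$max_zscr),
      sum_zscr = sum(sub$sum_zscr),
      output_zum2s = sum(sub$sum_zscr) * area * dt,
      centroid_row = mean(vx$row), centroid_col = mean(vx$col))
    voxels[[g]] <- vx
  }
  events <- do.call(rbind, events)
  ord <- order(events$onset_frame, events$centroid_row, events$centroid_col)
  events <- events[ord, ]
  voxels <- voxels[ord]
  events$event_id <- seq_len(nrow(events))
  rownames(events) <- NULL
  list(events = events, voxels = voxels)
}

#' Field-of-view activity summary
#'
#' Sums the integrated outputs of all ST objects and normalizes by the
#' recording length in minutes, giving the total Ca2+ "output" of the field
#' of view in Zum2s per minute.
#'
#' @param objects result of [track_st_objects()].
#' @param recording_duration_s recording length in seconds (> 0).
#' @return a list with `total_output_zum2s_per_min`, `n_events`,
#'   `recording_duration_min`, and the per-event table.
#' @export
summarize_fov <- function(objects, recording_duration_s) {
  if (recording_duration_s <= 0) stop("`recording_duration_s` must be > 0")
  minutes <- recording_duration_s / 60
  total <- sum(objects$events$output_zum2s) / minutes
  list(total_output_zum2s_per_min = total,
       n_events = nrow(objects$events),
       recording_duration_min = minutes,
       events = objects$events)
}

#' Run the full detection pipeline on a movie
#'
#' Convenience wrapper chaining the preprocessing steps (each optional),
#' pixel binning, quiescence estimation, Z-scoring, thresholded detection,
#' particle extraction, ST-object tracking and the FOV summary.
#'
#' @param movie a `MovieStack`.
#' @param stabilize_movie,debleach_model optional motion stabilization
#'   (logical) and debleach model (`NULL` to skip, else `"exponential"` or
#'   `"frame-mean"`); both off by default.
#' @param temporal_halfwidth,gauss_kernel,gauss_sd smoothing parameters
#'   (defaults 2 frames, 5 px, 1.0 px; set halfwidth 0 / kernel 1 to skip).
#' @param bin_size,quiescence_fraction,sd_multiplier quiescence-model
#'   parameters.
#' @param z_threshold,min_particle_px,connectivity detection parameters.
#' @param model optional precomputed `QuiescenceModel` to standardize with
#'   (used e.g. to score a noise-free reference movie with the statistics of
#'   its noisy counterpart); default `NULL` estimates the model from `movie`.
#' @return a list with `binned`, `model`, `z`, `objects`, `fov`, and
#'   `config` (the parameters used).
#' @details The temporal-average, spatial-smooth and binning stage is
#'   evaluated frame by frame (one output frame needs only its
#'   `2*halfwidth + 1` input frames), so full-resolution intermediate
#'   stacks are never materialized; the result is identical to chaining
#'   [temporal_average()], [spatial_smooth()] and [bin_pixels()].
#' @export
quantify_movie <- function(movie,
                           stabilize_movie = FALSE, debleach_model = NULL,
                           temporal_halfwidth = 2L, gauss_kernel = 5L,
                           gauss_sd = 1.0, bin_size = 10L,
                           quiescence_fraction = 0.20, sd_multiplier = 11.0,
                           z_threshold = 2.7, min_particle_px = 3L,
                           connectivity = 4L, model = NULL) {
  stopifnot(inherits(movie, "MovieStack"))
  if (isTRUE(stabilize_movie)) movie <- stabilize(movie)
  if (!is.null(debleach_model)) movie <- debleach(movie, debleach_model)
  d <- dim(movie$data)
  nf <- d[3]
  halfwidth <- as.integer(temporal_halfwidth)
  if (halfwidth > 0L && nf < 2L * halfwidth + 1L) {
    stop("too few frames for the temporal window")
  }
  taps <- if (gauss_kernel > 1L) gaussian_taps(as.integer(gauss_kernel),
                                               gauss_sd) else NULL
  bin_size <- as.integer(bin_size)
  if (bin_size < 1L || bin_size > min(d[1], d[2])) {
    stop("`bin_size` must be in 1..min(height, width)")
  }
  nbr <- d[1] %/% bin_size
  nbc <- d[2] %/% bin_size
  bdata <- array(0, dim = c(nbr, nbc, nf))
  hr <- nbr * bin_size
  hc <- nbc * bin_size
  for (f in seq_len(nf)) {
    lo <- max(1L, f - halfwidth)
    hi <- min(nf, f + halfwidth)
    fr <- if (hi > lo) {
      rowMeans(movie$data[, , lo:hi, drop = FALSE], dims = 2)
    } else movie$data[, , f]
    if (!is.null(taps)) fr <- smooth_frame(fr, taps)
    if (bin_size > 1L) {
      fr <- fr[seq_len(hr), seq_len(hc)]
      dim(fr) <- c(bin_size, nbr, bin_size, nbc)
      fr <- apply(fr, c(2, 4), sum) / bin_size^2
    }
    bdata[, , f] <- fr
  }
  eff <- bin_size * movie$pixel_size_um
  binned <- structure(
    list(data = bdata, bin_size_px = bin_size,
         effective_pixel_size_um = eff, bin_area_um2 = eff^2,
         frame_interval_s = movie$frame_interval_s),
    class = "BinnedMovie")
  if (is.null(model)) {
    model <- estimate_quiescence(binned, quiescence_fraction, sd_multiplier)
  }
  z <- zscore(binned, model)
  mask <- detect_active_mask(z, z_threshold, min_particle_px, connectivity)
  particles <- extract_particles(mask, z, connectivity)
  objects <- track_st_objects(particles, z)
  fov <- summarize_fov(objects, nf * movie$frame_interval_s)
  list(binned = binned, model = model, z = z, objects = objects, fov = fov,
       config = list(stabilize = stabilize_movie,
                     debleach_model = debleach_model,
                     temporal_halfwidth = halfwidth,
                     gauss_kernel = gauss_kernel, gauss_sd = gauss_sd,
                     bin_size = bin_size,
                     quiescence_fraction = quiescence_fraction,
                     sd_multiplier = sd_multiplier, z_threshold = z_threshold,
                     min_particle_px = min_particle_px,
                     connectivity = connectivity))
}

#' Match detected ST objects to ground-truth events
#'
#' Greedy one-to-one matching: each ground-truth event is paired with the
#' unmatched detected object whose frame span overlaps the truth window
#' (after optional symmetric broadening) and whose centroid, in bin
#' coordinates, is nearest the truth centroid.
#'
#' @param events detected event table from [track_st_objects()].
#' @param truth ground-truth table from [generate_movie()].
#' @param bin_size bin edge used in the pipeline, to convert truth pixel
#'   centroids to bin coordinates.
#' @param broaden_frames symmetric widening of the truth frame window before
#'   the overlap test (e.g. the temporal filter halfwidth); default 0.
#' @param max_dist_bins maximum allowed centroid distance (default 2 bins).
#' @return `truth` with columns `matched_event_id`, `det_n_frames`,
#'   `det_centroid_dist_bins` appended (`NA` where unmatched).
#' @export
match_events <- function(events, truth, bin_size = 10L, broaden_frames = 0L,
                         max_dist_bins = 2) {
  truth$matched_event_id <- NA_integer_
  truth$det_n_frames <- NA_integer_
  truth$det_centroid_dist_bins <- NA_real_
  used <- logical(nrow(events))
  for (i in seq_len(nrow(truth))) {
    t1 <- truth$onset_frame[i] - broaden_frames
    t2 <- truth$onset_frame[i] + truth$duration_frames[i] - 1L + broaden_frames
    tr <- (truth$centroid_row[i] - 0.5) / bin_size + 0.5
    tc <- (truth$centroid_col[i] - 0.5) / bin_size + 0.5
    cand <- which(!used & events$onset_frame <= t2 & events$end_frame >= t1)
    if (!length(cand)) next
    dist <- sqrt((events$centroid_row[cand] - tr)^2 +
                 (events$centroid_col[cand] - tc)^2)
    j <- cand[which.min(dist)]
    if (min(dist) > max_dist_bins) next
    used[j] <- TRUE
    truth$matched_event_id[i] <- events$event_id[j]
    truth$det_n_frames[i] <- events$n_frames[j]
    truth$det_centroid_dist_bins[i] <- min(dist)
  }
  truth
}
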