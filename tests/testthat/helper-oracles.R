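# Test helpers: small builders and brute-force oracles kept independent of
# the package's union-find / overlap-tracking implementation.

make_zmovie <- function(arr, bin_size = 10, pixel_size_um = 0.689,
                        frame_interval_s = 0.625) {
  d <- dim(arr)
  structure(list(data = arr,
                 bin_area_um2 = (bin_size * pixel_size_um)^2,
                 frame_interval_s = frame_interval_s,
                 valid = matrix(TRUE, d[1], d[2]),
                 quiescent_mask = array(TRUE, d)),
            class = "ZScoreMovie")
}

make_binned <- function(arr, bin_size = 10, pixel_size_um = 0.689,
                        frame_interval_s = 0.625) {
  eff <- bin_size * pixel_size_um
  structure(list(data = arr, bin_size_px = bin_size,
                 effective_pixel_size_um = eff, bin_area_um2 = eff^2,
                 frame_interval_s = frame_interval_s),
            class = "BinnedMovie")
}

# stack-based flood fill over a set of linear indices given a neighbor
# function; returns list of index vectors (one per component)
flood_components <- function(idx, neighbors) {
  comps <- list()
  seen <- new.env(hash = TRUE)
  inset <- new.env(hash = TRUE)
  for (i in idx) assign(as.character(i), TRUE, envir = inset)
  for (start in idx) {
    if (!is.null(seen[[as.character(start)]])) next
    stack <- start
    comp <- integer(0)
    seen[[as.character(start)]] <- TRUE
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      comp <- c(comp, cur)
      for (nb in neighbors(cur)) {
        key <- as.character(nb)
        if (!is.null(inset[[key]]) && is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          stack <- c(stack, nb)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# brute-force reference: threshold, per-frame removal of 2-D 4-connected
# components of <= min_px pixels, then 3-D 6-connected components; returns
# canonical sorted list of sorted voxel linear-index vectors
bf_st_voxel_sets <- function(zarr, z_threshold = 2.7, min_px = 3L) {
  d <- dim(zarr)
  mask <- !is.na(zarr) & zarr >= z_threshold
  nb2 <- function(i, nr, nc) {
    r <- (i - 1L) %% nr + 1L
    c <- (i - 1L) %/% nr + 1L
    out <- integer(0)
    if (r > 1L) out <- c(out, i - 1L)
    if (r < nr) out <- c(out, i + 1L)
    if (c > 1L) out <- c(out, i - nr)
    if (c < nc) out <- c(out, i + nr)
    out
  }
  for (f in seq_len(d[3])) {
    m <- mask[, , f]
    idx <- which(m)
    if (!length(idx)) next
    comps <- flood_components(idx, function(i) nb2(i, d[1], d[2]))
    for (comp in comps) if (length(comp) <= min_px) m[comp] <- FALSE
    mask[, , f] <- m
  }
  npf <- d[1] * d[2]
  nb3 <- function(i) {
    f <- (i - 1L) %/% npf + 1L
    j <- (i - 1L) %% npf + 1L
    r <- (j - 1L) %% d[1] + 1L
    c <- (j - 1L) %/% d[1] + 1L
    out <- integer(0)
    if (r > 1L) out <- c(out, i - 1L)
    if (r < d[1]) out <- c(out, i + 1L)
    if (c > 1L) out <- c(out, i - d[1])
    if (c < d[2]) out <- c(out, i + d[1])
    if (f > 1L) out <- c(out, i - npf)
    if (f < d[3]) out <- c(out, i + npf)
    out
  }
  idx <- which(mask)
  comps <- flood_components(idx, nb3)
  comps[order(vapply(comps, min, numeric(1)))]
}

# canonical voxel sets from the package's detect -> extract -> track chain
chain_st_voxel_sets <- function(z, z_threshold = 2.7, min_px = 3L) {
  mask <- detect_active_mask(z, z_threshold, min_px)
  particles <- extract_particles(mask, z)
  objects <- track_st_objects(particles, z)
  d <- dim(z$data)
  sets <- lapply(objects$voxels, function(v) {
    sort(v$row + (v$col - 1L) * d[1] + (v$frame - 1L) * d[1] * d[2])
  })
  sets[order(vapply(sets, min, numeric(1)))]
}

# random small Z movie: unit noise plus a few planted suprathreshold blobs
random_z_array <- function(d = c(10, 10, 12), n_blobs = 2) {
  arr <- array(stats::rnorm(prod(d), sd = 1.2), dim = d)
  for (b in seq_len(n_blobs)) {
    r0 <- sample.int(d[1] - 2L, 1L)
    c0 <- sample.int(d[2] - 2L, 1L)
    f0 <- sample.int(d[3] - 3L, 1L)
    arr[r0:(r0 + 2L), c0:(c0 + 2L), f0:(f0 + 2L)] <-
      stats::runif(27, 4, 12)
  }
  arr
}

# small generator setup used across pipeline tests
small_movie_params <- function(seed = 7, n_events = 3, amplitude = 8,
                               duration_frames = 8, ...) {
  movie_params(n_frames = 120, height = 120, width = 120, n_cells = 8,
               events = event_plan(n = n_events, amplitude = amplitude,
                                   duration_frames = duration_frames,
                                   footprint_px = 300, min_sep_px = 40,
                                   margin_frames = 10),
               seed = seed, ...)
}
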