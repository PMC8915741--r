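test_that("identical parameters and seed reproduce the movie bit for bit", {
  p <- small_movie_params(seed = 3)
  g1 <- generate_movie(p)
  g2 <- generate_movie(p)
  expect_identical(g1$movie$data, g2$movie$data)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_movie(small_movie_params(seed = 4))
  expect_false(identical(g1$movie$data, g3$movie$data))
})

test_that("an event-free request yields baseline plus noise only", {
  p <- movie_params(n_frames = 30, height = 60, width = 60, n_cells = 2,
                    seed = 5)
  g <- generate_movie(p, keep_signal = TRUE)
  expect_equal(nrow(g$truth), 0)
  # the noise-free signal is the static baseline in every frame
  expect_true(all(g$signal == g$signal[, , rep(1, 30)]))
  # rendered intensities are 16-bit integer counts
  expect_true(all(g$movie$data == round(g$movie$data)))
  expect_true(max(g$movie$data) <= 65535)
})

test_that("rendered plateau amplitude recovers the requested multiple of the local noise SD", {
  p <- small_movie_params(seed = 11, n_events = 5, amplitude = 8,
                          duration_frames = 8)
  g <- generate_movie(p, keep_signal = TRUE)
  expect_equal(nrow(g$truth), 5)
  for (k in seq_len(5)) {
    fp <- g$footprints[[k]]
    idx <- fp[, 1] + (fp[, 2] - 1L) * 120L
    onset <- g$truth$onset_frame[k]
    plateau <- (onset + 1L):(onset + g$truth$duration_frames[k] - 3L)
    base <- g$signal[, , 1][idx]
    local_sd <- p$noise_sd * sqrt(base / p$noise_ref)
    rendered <- rowMeans(sapply(plateau, function(f) g$signal[, , f][idx])) - base
    ratio <- mean(rendered) / mean(8 * local_sd)
    expect_lt(abs(ratio - 1), 0.10)
    # the noisy rendering agrees once averaged over the footprint
    noisy <- rowMeans(sapply(plateau, function(f) g$movie$data[, , f][idx])) - base
    expect_lt(abs(mean(noisy) / mean(8 * local_sd) - 1), 0.10)
  }
})

test_that("invalid event specifications are rejected with a message", {
  base <- function(events) {
    movie_params(n_frames = 20, height = 60, width = 60, n_cells = 1,
                 events = events, seed = 1)
  }
  out_of_bounds <- list(list(footprint = cbind(row = 59:61, col = 5:7),
                             onset_frame = 5, duration_frames = 4,
                             amplitude = 5))
  expect_error(generate_movie(base(out_of_bounds)), "outside")
  fp <- cbind(row = 10:14, col = rep(10, 5))
  overlapping <- list(
    list(footprint = fp, onset_frame = 5, duration_frames = 6, amplitude = 5),
    list(footprint = fp[2:4, , drop = FALSE], onset_frame = 8,
         duration_frames = 4, amplitude = 5))
  expect_error(generate_movie(base(overlapping)), "overlaps")
  # same pixels at disjoint times are fine
  sequential <- list(
    list(footprint = fp, onset_frame = 2, duration_frames = 4, amplitude = 5),
    list(footprint = fp, onset_frame = 10, duration_frames = 4, amplitude = 5))
  expect_silent(g <- generate_movie(base(sequential)))
  expect_equal(nrow(g$truth), 2)
})

test_that("default event loads leave every pixel quiescent for at least 20% of frames", {
  g <- generate_movie(small_movie_params(seed = 21, n_events = 4))
  touched <- array(FALSE, dim = dim(g$movie$data))
  for (k in seq_len(4)) {
    fp <- g$footprints[[k]]
    fr <- g$truth$onset_frame[k]:(g$truth$onset_frame[k] +
                                  g$truth$duration_frames[k] - 1L)
    for (f in fr) touched[cbind(fp[, 1], fp[, 2], f)] <- TRUE
  }
  event_frames_per_px <- apply(touched, c(1, 2), sum)
  expect_lte(max(event_frames_per_px) / dim(touched)[3], 0.8)
})
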