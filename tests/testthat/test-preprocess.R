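drifting_movie <- function(drift = c(1, 1), n_frames = 5) {
  generate_movie(movie_params(n_frames = n_frames, height = 80, width = 80,
                              n_cells = 4, noise_sd = 5,
                              drift_px_per_frame = drift, seed = 13))$movie
}

test_that("stabilization leaves a drift-free movie in place and recovers injected drift", {
  still <- drifting_movie(drift = c(0, 0))
  st <- stabilize(still)
  prov <- st$provenance[[length(st$provenance)]]
  expect_true(all(prov$shifts == 0))
  expect_equal(st$data, still$data)

  moving <- drifting_movie(drift = c(1, 1))
  st <- stabilize(moving, max_shift_px = 6)
  prov <- st$provenance[[length(st$provenance)]]
  # frame f was rendered shifted by (f-1, f-1); the correction undoes it
  expect_equal(prov$shifts,
               matrix(-(seq_len(5) - 1L), 5, 2), ignore_attr = TRUE)

  one <- movie_stack(array(1, dim = c(8, 8, 1)))
  expect_error(stabilize(one), "2 frames")
})

test_that("debleaching flattens exponential decay and preserves constants", {
  const <- movie_stack(array(100, dim = c(10, 10, 20)))
  out <- debleach(const, "frame-mean")
  expect_equal(out$data, const$data)

  decay <- exp(-(0:19) * 0.625 / 30)
  m <- movie_stack(array(rep(200 * decay, each = 100), dim = c(10, 10, 20)))
  out <- debleach(m, "exponential")
  means <- apply(out$data, 3, mean)
  expect_true(all(abs(means / means[1] - 1) < 0.01))

  zero <- movie_stack(array(0, dim = c(4, 4, 3)))
  expect_error(debleach(zero), "zero mean")
})

test_that("debleaching preserves relative event amplitude while flattening baseline", {
  nf <- 60
  decay <- exp(-(seq_len(nf) - 1) * 0.625 / 120)
  arr <- array(rep(1000 * decay, each = 400), dim = c(20, 20, nf))
  ev_px <- cbind(rep(5:8, 4), rep(5:8, each = 4))
  ev_fr <- 20:27
  # the event fluorescence bleaches with the rest of the dye
  for (f in ev_fr) arr[cbind(ev_px, f)] <- arr[cbind(ev_px, f)] + 100 * decay[f]
  out <- debleach(movie_stack(arr), "exponential")
  # quiescent-pixel frame means flat
  q_means <- apply(out$data[15:20, 15:20, ], 3, mean)
  expect_true(all(abs(q_means / q_means[1] - 1) < 0.01))
  # event step (event frames minus surrounding baseline at the same pixels)
  step <- mean(out$data[cbind(ev_px[1, 1], ev_px[1, 2], ev_fr)]) -
    mean(out$data[ev_px[1, 1], ev_px[1, 2], c(10:17, 30:37)])
  expect_lt(abs(step / 100 - 1), 0.02)
})

test_that("temporal averaging is a truncated box filter that reports its window", {
  const <- movie_stack(array(3, dim = c(6, 6, 11)))
  out <- temporal_average(const)
  expect_equal(out$data, const$data)
  prov <- out$provenance[[length(out$provenance)]]
  # 5 frames x 0.625 s = 3.125 s, the reported "3.13 s" window
  expect_equal(prov$window_s, 3.125)
  expect_lt(abs(prov$window_s - 3.13), 0.005)

  arr <- array(0, dim = c(5, 5, 15))
  arr[3, 3, 8] <- 1
  out <- temporal_average(movie_stack(arr), 2)
  expect_equal(out$data[3, 3, ], c(rep(0, 5), rep(0.2, 5), rep(0, 5)))
  expect_equal(sum(out$data), 1)

  short <- movie_stack(array(1, dim = c(4, 4, 3)))
  expect_error(temporal_average(short, 2), "few frames")
})

test_that("spatial smoothing uses a normalized Gaussian with reflected borders", {
  const <- movie_stack(array(7, dim = c(12, 12, 2)))
  out <- spatial_smooth(const)
  expect_equal(out$data, const$data)

  arr <- array(0, dim = c(11, 11, 1))
  arr[6, 6, 1] <- 1
  out <- spatial_smooth(movie_stack(arr), 5, 1.0)
  # oracle: brute-force normalized 5x5 Gaussian
  g <- exp(-outer((-2:2)^2, (-2:2)^2, "+") / 2)
  k <- g / sum(g)
  expect_equal(out$data[6, 6, 1], k[3, 3], tolerance = 1e-12)
  expect_equal(out$data[4:8, 4:8, 1], k, tolerance = 1e-12)
  # interior support: total intensity preserved
  expect_lt(abs(sum(out$data) - 1), 1e-6)

  expect_error(spatial_smooth(const, 4), "odd")
})

test_that("preprocessing preserves geometry and is non-expansive where it should be", {
  g <- generate_movie(movie_params(n_frames = 12, height = 60, width = 60,
                                   n_cells = 1, seed = 6))
  m <- g$movie
  for (op in list(function(x) temporal_average(x, 2),
                  function(x) spatial_smooth(x, 5, 1),
                  function(x) debleach(x, "frame-mean"))) {
    out <- op(m)
    expect_equal(dim(out$data), dim(m$data))
    expect_equal(out$pixel_size_um, m$pixel_size_um)
    expect_equal(out$frame_interval_s, m$frame_interval_s)
  }
  sm <- spatial_smooth(temporal_average(m, 2), 5, 1)
  expect_lte(max(sm$data), max(m$data))
  expect_gte(min(sm$data), min(m$data))
})

test_that("replaying the provenance log reproduces the output bit for bit", {
  raw <- generate_movie(movie_params(n_frames = 12, height = 60, width = 60,
                                     n_cells = 2, bleach_tau_s = 200,
                                     seed = 8))$movie
  pre <- spatial_smooth(temporal_average(debleach(raw, "exponential"), 2), 5, 1)
  replay <- apply_chain(raw, pre$provenance)
  expect_identical(replay$data, pre$data)
})
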