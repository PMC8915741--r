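test_that("pixel binning crops to whole bins and averages blocks", {
  const <- movie_stack(array(4, dim = c(512, 512, 3)))
  b <- bin_pixels(const, 10)
  expect_equal(dim(b$data), c(51, 51, 3))
  expect_true(all(b$data == 4))
  expect_equal(b$effective_pixel_size_um, 6.89)
  expect_equal(b$bin_area_um2, 6.89^2)

  checker <- movie_stack(array(outer(1:4, 1:4, function(r, c) (r + c) %% 2),
                               dim = c(4, 4, 1)))
  b2 <- bin_pixels(checker, 2)
  expect_true(all(b2$data == 0.5))

  m <- generate_movie(movie_params(n_frames = 4, height = 30, width = 30,
                                   n_cells = 1, seed = 3))$movie
  expect_identical(bin_pixels(m, 1)$data, m$data)
  expect_error(bin_pixels(m, 40), "frame size")
})

noise_binned <- function(nf = 500, d = c(4, 4), mu = 100, sigma = 5, seed = 1) {
  set.seed(seed)
  make_binned(array(stats::rnorm(prod(d) * nf, mu, sigma), dim = c(d, nf)))
}

test_that("quiescence statistics recover the noise parameters of inactive pixels", {
  b <- noise_binned()
  q <- estimate_quiescence(b)
  expect_true(all(q$valid))
  expect_true(all(abs(q$sd_q / 5 - 1) < 0.15))
  expect_true(all(abs(q$avg_q - 100) < 0.5))
})

test_that("the quiescent mask excludes frames in which the pixel is active", {
  b <- noise_binned(seed = 4)
  active <- seq(1, 500, by = 2)
  b$data[1, 1, active] <- b$data[1, 1, active] + 20 * 5
  q <- estimate_quiescence(b)
  expect_true(q$valid[1, 1])
  expect_false(any(q$quiescent_mask[1, 1, active]))
  expect_true(all(q$quiescent_mask[1, 1, -active]))
})

test_that("degenerate pixels are flagged invalid and parameters validated", {
  b <- noise_binned(seed = 5)
  b$data[2, 2, ] <- 50
  q <- estimate_quiescence(b)
  expect_false(q$valid[2, 2])
  expect_equal(q$sd_qmin[2, 2], 0)
  z <- zscore(b, q)
  expect_true(all(is.na(z$data[2, 2, ])))
  expect_error(estimate_quiescence(b, quiescence_fraction = 0), "quiescence_fraction")
  expect_error(estimate_quiescence(b, quiescence_fraction = 1.5), "quiescence_fraction")
})

test_that("Z-scores obey the defining identities at the detection threshold", {
  b <- noise_binned(seed = 6)
  q <- estimate_quiescence(b)
  b$data[1, 1, 1] <- q$avg_q[1, 1]
  b$data[1, 2, 1] <- q$avg_q[1, 2] + 2.7 * q$sd_q[1, 2]
  z <- zscore(b, q)
  expect_equal(z$data[1, 1, 1], 0, tolerance = 1e-12)
  expect_equal(z$data[1, 2, 1], 2.7, tolerance = 1e-12)
  bad <- noise_binned(nf = 20, d = c(3, 3), seed = 7)
  expect_error(zscore(bad, q), "geometries")
})

test_that("quiescent-sample Z-scores standardize exactly and cover the assumed fraction", {
  b <- noise_binned(seed = 8)
  q <- estimate_quiescence(b)
  z <- zscore(b, q)
  for (i in 1:4) for (j in 1:4) {
    zq <- z$data[i, j, q$quiescent_mask[i, j, ]]
    expect_lt(abs(mean(zq)), 1e-9)
    expect_lt(abs(stats::sd(zq) - 1), 1e-9)
    expect_gte(length(zq) / 500, 0.20)
  }
})

test_that("Z is strictly increasing in raw intensity and invariant to intensity rescaling", {
  b <- noise_binned(seed = 9)
  q <- estimate_quiescence(b)
  z <- zscore(b, q)
  expect_equal(order(b$data[3, 3, ]), order(z$data[3, 3, ]))
  for (c_scale in c(0.25, 7)) {
    b2 <- b
    b2$data <- b2$data * c_scale
    z2 <- zscore(b2, estimate_quiescence(b2))
    expect_lt(max(abs(z2$data - z$data)), 1e-9)
  }
})

test_that("whole-recording z-mean of a no-event movie is standardized", {
  g <- generate_movie(movie_params(n_frames = 200, height = 80, width = 80,
                                   n_cells = 6, seed = 10))
  res <- quantify_movie(g$movie, temporal_halfwidth = 0L, gauss_kernel = 1L)
  zq <- res$z$data[res$model$quiescent_mask]
  zq <- zq[!is.na(zq)]
  expect_lt(abs(mean(zq)), 0.05)
  expect_lt(abs(stats::sd(zq) - 1), 0.1)
})
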