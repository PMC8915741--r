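blank_z <- function(d = c(8, 8, 6)) make_zmovie(array(0, dim = d))

test_that("thresholding is inclusive at 2.7 and the particle filter drops <= 3-pixel blobs", {
  z <- blank_z()
  expect_false(any(detect_active_mask(z)))

  z$data[2, 2, 1] <- 2.7                      # exactly at threshold, isolated
  z$data[2, 2:5, 2] <- 5                      # 4-pixel line, kept
  z$data[5, 5:7, 2] <- 5                      # 3-pixel line, removed
  mask <- detect_active_mask(z, min_particle_px = 0)
  expect_true(mask[2, 2, 1])                  # >= is inclusive
  mask <- detect_active_mask(z)
  expect_false(mask[2, 2, 1])
  expect_true(all(mask[2, 2:5, 2]))
  expect_false(any(mask[5, 5:7, 2]))
})

test_that("particles carry pixel counts, areas and Z summaries", {
  z <- blank_z()
  z$data[2, 2:5, 1] <- c(3, 4, 5, 6)
  z$data[6:7, 6:7, 1] <- 5
  p <- extract_particles(detect_active_mask(z), z)
  expect_equal(nrow(p$table), 2)
  blob <- p$table[p$table$n_px == 4 & p$table$max_zscr == 6, ]
  expect_equal(blob$area_um2, 4 * (10 * 0.689)^2)
  expect_equal(round(blob$area_um2, 1), 189.9)
  expect_equal(blob$max_zscr, 6)
  expect_equal(blob$sum_zscr, 18)
})

test_that("overlap tracking links consecutive frames and never bridges gaps", {
  z <- blank_z(c(8, 8, 10))
  z$data[2:3, 2:3, 3:7] <- 6                  # persists frames 3-7
  obj <- track_st_objects(extract_particles(detect_active_mask(z), z), z)
  expect_equal(nrow(obj$events), 1)
  expect_equal(obj$events$n_frames, 5)
  expect_equal(obj$events$duration_s, 5 * 0.625)

  z2 <- blank_z(c(8, 8, 5))
  z2$data[2:3, 2:3, 1] <- 6
  z2$data[2:3, 2:3, 3] <- 6                   # same blob, frame 2 silent
  obj2 <- track_st_objects(extract_particles(detect_active_mask(z2), z2), z2)
  expect_equal(nrow(obj2$events), 2)
})

test_that("merging blobs coalesce into one object, matching the 3-D oracle", {
  z <- blank_z(c(6, 6, 6))
  z$data[1:2, 1:2, 1:3] <- 6
  z$data[5:6, 1:2, 1:3] <- 6
  z$data[1:6, 1:2, 4] <- 6                    # bridge joins both in frame 4
  sets <- chain_st_voxel_sets(z)
  expect_equal(length(sets), 1)
  expect_identical(sets, bf_st_voxel_sets(z$data))
})

test_that("detect-extract-track equals brute-force 3-D connected components on random movies", {
  set.seed(42)
  for (rep in 1:12) {
    arr <- random_z_array(d = c(sample(6:12, 1), sample(6:12, 1),
                                sample(8:20, 1)),
                          n_blobs = sample(0:3, 1))
    z <- make_zmovie(arr)
    expect_identical(chain_st_voxel_sets(z), bf_st_voxel_sets(arr))
  }
})

test_that("the FOV summary integrates Z x area x time and normalizes per minute", {
  z <- blank_z(c(8, 8, 144))                  # 90 s at 0.625 s/frame
  z$data[2:3, 2:6, 10:13] <- 3                # 10 bins x 4 frames, Z = 3
  obj <- track_st_objects(extract_particles(detect_active_mask(z), z), z)
  fov <- summarize_fov(obj, 144 * 0.625)
  manual <- 3 * 10 * (10 * 0.689)^2 * 0.625 * 4 / 1.5
  expect_equal(fov$total_output_zum2s_per_min, manual, tolerance = 1e-12)
  expect_equal(round(manual, 1), 2373.6)
  expect_equal(fov$n_events, 1)

  empty <- summarize_fov(track_st_objects(
    extract_particles(detect_active_mask(blank_z()), blank_z()), blank_z()), 90)
  expect_equal(empty$total_output_zum2s_per_min, 0)
  expect_error(summarize_fov(obj, 0), "> 0")
})

test_that("FOV output is additive over disjoint objects and conserves the voxel integral", {
  z <- blank_z(c(10, 10, 20))
  z$data[2:3, 2:4, 3:6] <- 5
  z$data[7:8, 6:8, 10:14] <- 4
  mask <- detect_active_mask(z)
  obj <- track_st_objects(extract_particles(mask, z), z)
  expect_equal(nrow(obj$events), 2)
  fov <- summarize_fov(obj, 20 * 0.625)
  voxel_integral <- sum(z$data[mask]) * z$bin_area_um2 * z$frame_interval_s
  expect_equal(sum(obj$events$output_zum2s), voxel_integral,
               tolerance = 1e-6)
  expect_equal(fov$total_output_zum2s_per_min,
               sum(obj$events$output_zum2s) / (20 * 0.625 / 60))
})
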