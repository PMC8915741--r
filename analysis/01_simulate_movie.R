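#!/usr/bin/env Rscript
# Simulate a dye-loaded urothelial sheet with known Ca2+ events.
#
# Produces a demonstration-scale movie (256 x 256 px, 300 frames, 8 events
# of amplitude 8x the local noise SD) plus its ground-truth event table.
# The movie itself goes to scratch/ (binary, regenerable); the ground truth
# and generator parameters go to results/ as text.

library(caquant)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

params <- movie_params(
  n_frames = 300, height = 256, width = 256, n_cells = 24,
  events = event_plan(n = 8, amplitude = 8, duration_frames = 8,
                      footprint_px = 800, min_sep_px = 70),
  seed = 20260101)
gen <- generate_movie(params)

write_movie(gen$movie, "scratch/demo_movie.tif")
write.csv(gen$truth, "results/demo_ground_truth.csv", row.names = FALSE)
jsonlite::write_json(params[setdiff(names(params), "events")],
                     "results/demo_movie_params.json",
                     auto_unbox = TRUE, digits = NA)

cat(sprintf(
  "Simulated %d x %d px, %d-frame sheet with %d cells and %d events\n",
  params$height, params$width, params$n_frames, params$n_cells,
  nrow(gen$truth)))
cat(sprintf("  event onsets (frames): %s\n",
            paste(sort(gen$truth$onset_frame), collapse = ", ")))
cat("  movie -> scratch/demo_movie.tif; truth -> results/demo_ground_truth.csv\n")
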