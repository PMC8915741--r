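Package: caquant
Title: Calcium Event Detection and Voiding Analysis for Urothelial Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detection and quantification of calcium transients in time-lapse
    fluorescence movies of intact urothelial sheets. Implements a per-pixel
    quiescence-based noise model (SDqmin, quiescent-period AVGq/SDq), Z-score
    conversion, thresholded spatio-temporal event objects, and the integrated
    Zum2s activity output, together with seeded synthetic-movie and synthetic
    voiding-session generators with known ground truth, natural-voiding assay
    metrics (void counts, intermicturition intervals, void mass in 4-h
    windows), and paired-design effect statistics (paired t, Cohen's d, fold
    and percent change).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
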