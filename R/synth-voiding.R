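#' Parameters for the synthetic voiding-session generator
#'
#' Emulates a 24-h metabolic-cage assessment: void times form a renewal
#' process with gamma-distributed inter-void intervals (IMIs) and void
#' masses are drawn i.i.d. from a positive-truncated normal. The default
#' exponential IMI (shape 1) keeps renewal expectations exact (expected
#' void count = duration / mean IMI); larger shapes give the more regular
#' voiding rhythm of real animals.
#'
#' @param duration_h session length in hours (default 24).
#' @param imi_mean_min mean inter-void interval in minutes (default 120).
#' @param imi_shape gamma shape of the IMI distribution (default 1,
#'   i.e. exponential).
#' @param mass_mean_g,mass_sd_g void mass distribution in grams
#'   (defaults 1.5, 0.3; draws truncated to be positive).
#' @param water_intake_ml water intake over the session in mL (default 30).
#' @param seed integer seed (default 1).
#' @return a validated parameter list of class `voiding_params`.
#' @export
voiding_params <- function(duration_h = 24, imi_mean_min = 120,
                           imi_shape = 1, mass_mean_g = 1.5,
                           mass_sd_g = 0.3, water_intake_ml = 30,
                           seed = 1L) {
  stopifnot(imi_mean_min > 0, imi_shape > 0, mass_mean_g > 0,
            mass_sd_g > 0, water_intake_ml > 0)
  if (duration_h <= 0) stop("`duration_h` must be > 0")
  structure(list(duration_h = duration_h, imi_mean_min = imi_mean_min,
                 imi_shape = imi_shape, mass_mean_g = mass_mean_g,
                 mass_sd_g = mass_sd_g, water_intake_ml = water_intake_ml,
                 seed = as.integer(seed)),
            class = "voiding_params")
}

#' Construct a voiding session
#'
#' @param times_s void times in seconds from session start, strictly
#'   increasing within `[0, duration_h * 3600]`.
#' @param masses_g void masses in grams (> 0), matched to `times_s`.
#' @param water_intake_ml water intake over the session in mL.
#' @param duration_h session length in hours (default 24).
#' @param label `"baseline"` or `"treatment"`.
#' @return an object of class `VoidingSession`.
#' @export
voiding_session <- function(times_s, masses_g, water_intake_ml,
                            duration_h = 24, label = "baseline") {
  if (length(times_s) != length(masses_g)) stop("times and masses differ in length")
  if (length(times_s) && (any(diff(times_s) <= 0) ||
                          any(times_s < 0 | times_s > duration_h * 3600))) {
    stop("void times must be strictly increasing within the session")
  }
  if (any(masses_g <= 0)) stop("void masses must be > 0")
  structure(list(voids = data.frame(time_s = as.numeric(times_s),
                                    mass_g = as.numeric(masses_g)),
                 water_intake_ml = water_intake_ml,
                 duration_h = duration_h, label = label),
            class = "VoidingSession")
}

#' Generate a seeded synthetic voiding session
#'
#' @param params a [voiding_params()] object.
#' @param label session label (default `"baseline"`).
#' @return a `VoidingSession`.
#' @export
generate_voiding_session <- function(params, label = "baseline") {
  stopifnot(inherits(params, "voiding_params"))
  p <- params
  set.seed(p$seed)
  total_s <- p$duration_h * 3600
  scale_s <- p$imi_mean_min * 60 / p$imi_shape
  times <- numeric(0)
  t <- 0
  repeat {
    t <- t + stats::rgamma(1, shape = p$imi_shape, scale = scale_s)
    if (t > total_s) break
    times <- c(times, t)
  }
  masses <- numeric(length(times))
  for (i in seq_along(masses)) {
    repeat {
      m <- stats::rnorm(1, p$mass_mean_g, p$mass_sd_g)
      if (m > 0) break
    }
    masses[i] <- m
  }
  voiding_session(times, masses, p$water_intake_ml, p$duration_h, label)
}

#' Inter-void intervals of a session, in minutes
#'
#' Intervals between consecutive voids, the session start counting as a
#' renewal epoch (so the first interval is start-to-first-void).
#'
#' @param session a `VoidingSession`.
#' @param include_first include the start-to-first-void interval
#'   (default `TRUE`).
#' @return numeric vector of intervals in minutes.
#' @export
session_intervals_min <- function(session, include_first = TRUE) {
  t <- session$voids$time_s
  if (!length(t)) return(numeric(0))
  iv <- if (include_first) diff(c(0, t)) else diff(t)
  iv / 60
}
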