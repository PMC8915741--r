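#' Summarize a voiding session in fixed windows
#'
#' Assigns voids to half-open windows `[k*w, (k+1)*w)` hours from session
#' start (a void at exactly 4 h belongs to the 4-8 h window) and computes,
#' per window, the void count, the mean inter-void interval (IMI, minutes;
#' each interval between consecutive voids is attributed to the window
#' containing the later void, `NA` when no interval ends in the window) and
#' the mean void mass, plus session totals.
#'
#' @param session a `VoidingSession`.
#' @param window_h window width in hours (default 4).
#' @return a `VoidingSummary`: list with `windows` (data frame:
#'   `window`, `start_h`, `end_h`, `n_voids`, `mean_imi_min`,
#'   `mean_void_mass_g`), `total_voids`, `total_mass_g`,
#'   `water_intake_ml`, `label`.
#' @export
summarize_session <- function(session, window_h = 4) {
  stopifnot(inherits(session, "VoidingSession"))
  t <- session$voids$time_s
  if (length(t) > 1 && any(diff(t) <= 0)) stop("void times must be increasing")
  nw <- ceiling(session$duration_h / window_h)
  w_s <- window_h * 3600
  win_of <- function(x) pmin(floor(x / w_s), nw - 1) + 1
  v_win <- if (length(t)) win_of(t) else integer(0)
  imi <- if (length(t) >= 2) diff(t) / 60 else numeric(0)
  imi_win <- if (length(t) >= 2) v_win[-1] else integer(0)
  windows <- data.frame(
    window = seq_len(nw),
    start_h = (seq_len(nw) - 1) * window_h,
    end_h = seq_len(nw) * window_h,
    n_voids = vapply(seq_len(nw), function(k) sum(v_win == k), integer(1)),
    mean_imi_min = vapply(seq_len(nw), function(k) {
      x <- imi[imi_win == k]
      if (length(x)) mean(x) else NA_real_
    }, numeric(1)),
    mean_void_mass_g = vapply(seq_len(nw), function(k) {
      x <- session$voids$mass_g[v_win == k]
      if (length(x)) mean(x) else NA_real_
    }, numeric(1)))
  structure(list(windows = windows,
                 total_voids = length(t),
                 total_mass_g = sum(session$voids$mass_g),
                 water_intake_ml = session$water_intake_ml,
                 label = session$label),
            class = "VoidingSummary")
}

#' Water-intake exclusion rule for paired assessments
#'
#' A subject is excluded when its water intake in the experimental
#' assessment exceeds the baseline intake by more than 20% (strictly over;
#' exactly +20% is kept), so that voiding-frequency changes cannot be
#' attributed to polydipsia.
#'
#' @param baseline,experimental `VoidingSession`s of the same subject.
#' @return `"keep"` or `"exclude"`.
#' @export
exclusion_check <- function(baseline, experimental) {
  b <- baseline$water_intake_ml
  e <- experimental$water_intake_ml
  if (is.null(b) || is.null(e)) stop("water intake missing")
  if (b <= 0) stop("baseline water intake must be > 0")
  if (e > 1.20 * b) "exclude" else "keep"
}

#' Paired per-window percent changes between assessments
#'
#' For matched baseline/treatment summaries (same subjects, same order),
#' computes per subject and window the percent change
#' `100 * (treatment - baseline) / baseline` of the void count, mean IMI and
#' mean void mass, and the group mean +/- SEM per window and metric. Cells
#' with an undefined or zero baseline are flagged `NA`.
#'
#' @param baselines,treatments lists of `VoidingSummary` objects.
#' @return list with `subjects` (long data frame: `subject`, `window`,
#'   `metric`, `baseline`, `treatment`, `pct_change`) and `group`
#'   (`window`, `metric`, `mean_pct_change`, `sem_pct_change`, `n`).
#' @export
paired_window_changes <- function(baselines, treatments) {
  if (length(baselines) != length(treatments)) {
    stop("baseline and treatment lists must be matched per subject")
  }
  metrics <- c(n_voids = "n_voids", mean_imi_min = "mean_imi_min",
               mean_void_mass_g = "mean_void_mass_g")
  rows <- list()
  for (s in seq_along(baselines)) {
    bw <- baselines[[s]]$windows
    tw <- treatments[[s]]$windows
    if (nrow(bw) != nrow(tw)) stop("window layouts differ between arms")
    for (m in names(metrics)) {
      b <- bw[[m]]
      tr <- tw[[m]]
      pct <- ifelse(!is.na(b) & !is.na(tr) & b != 0,
                    100 * (tr - b) / b, NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, window = bw$window, metric = m,
        baseline = as.numeric(b), treatment = as.numeric(tr),
        pct_change = pct)
    }
  }
  subjects <- do.call(rbind, rows)
  agg <- split(subjects, list(subjects$window, subjects$metric), drop = TRUE)
  group <- do.call(rbind, lapply(agg, function(g) {
    x <- g$pct_change[!is.na(g$pct_change)]
    data.frame(window = g$window[1], metric = g$metric[1],
               mean_pct_change = if (length(x)) mean(x) else NA_real_,
               sem_pct_change = if (length(x) > 1)
                 stats::sd(x) / sqrt(length(x)) else NA_real_,
               n = length(x))
  }))
  group <- group[order(group$metric, group$window), ]
  rownames(group) <- NULL
  list(subjects = subjects, group = group)
}

#' Segment a cumulative balance trace into discrete voids
#'
#' Metabolic-cage software logs the cumulative mass on the collection
#' balance; a void appears as a step increase. Steps of at least
#' `min_void_g` are taken as voids (timestamped at the sample where the
#' increase is recorded); smaller increments are treated as balance jitter
#' and ignored.
#'
#' @param trace data frame with `time_s` (increasing) and `balance_g`.
#' @param min_void_g minimum detectable void mass in grams (default 0.1).
#' @param water_intake_ml,duration_h,label session metadata passed through
#'   to the returned `VoidingSession`.
#' @return a `VoidingSession`.
#' @export
segment_cumulative_trace <- function(trace, min_void_g = 0.1,
                                     water_intake_ml = NA_real_,
                                     duration_h = 24, label = "baseline") {
  if (any(diff(trace$time_s) <= 0)) stop("trace times must be increasing")
  inc <- diff(trace$balance_g)
  hit <- which(inc >= min_void_g)
  voiding_session(trace$time_s[hit + 1L], inc[hit], water_intake_ml,
                  duration_h, label)
}
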