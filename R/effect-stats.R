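#' @title Paired-design effect statistics
#' @description Within-subject comparisons of activity and voiding metrics:
#'   variance-stabilizing transforms (square root for counts, natural log
#'   for intervals and masses), the classical paired t-test, Cohen's d
#'   (difference-score form by default, pooled-SD form available), and
#'   fold / percent change relative to baseline.
#' @name effect-stats
NULL

apply_transform <- function(x, transform) {
  switch(transform,
         none = x,
         sqrt = {
           if (any(x < 0)) stop("square-root transform needs non-negative values")
           sqrt(x)
         },
         log = {
           if (any(x <= 0)) stop("natural-log transform needs positive values")
           log(x)
         },
         stop(sprintf("unknown transform '%s'", transform)))
}

#' Paired t-test on optionally transformed values
#'
#' Classical two-sided paired Student's t on matched vectors, after applying
#' the same variance-stabilizing transform to both arms.
#'
#' @param baseline,treatment matched numeric vectors (n >= 2).
#' @param transform `"none"` (default), `"sqrt"`, or `"log"` (natural log).
#' @return list with `t_statistic`, `p_value`, `df`, `mean_difference`
#'   (treatment minus baseline, on the transformed scale), `transform`.
#' @export
paired_t <- function(baseline, treatment, transform = c("none", "sqrt", "log")) {
  transform <- match.arg(transform)
  if (length(baseline) != length(treatment)) stop("arms must be matched")
  if (length(baseline) < 2) stop("need at least 2 pairs")
  a <- apply_transform(baseline, transform)
  b <- apply_transform(treatment, transform)
  d <- b - a
  if (stats::sd(d) == 0) {
    stop("differences have zero variance; paired t is undefined")
  }
  ht <- stats::t.test(b, a, paired = TRUE)
  list(t_statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), mean_difference = mean(d),
       transform = transform)
}

#' Cohen's d effect size
#'
#' Paired (difference-score) form `mean(d) / sd(d)` by default, matching a
#' within-subject design where each preparation is compared to its own
#' baseline; the unpaired form uses the pooled standard deviation.
#'
#' @param baseline,treatment numeric vectors (matched when `paired`).
#' @param paired use the difference-score form (default `TRUE`).
#' @return list with `d` and `convention` (`"paired"` or `"pooled"`).
#' @export
cohens_d <- function(baseline, treatment, paired = TRUE) {
  if (length(baseline) < 2 || length(treatment) < 2) stop("need n >= 2")
  if (paired) {
    if (length(baseline) != length(treatment)) stop("arms must be matched")
    d <- treatment - baseline
    s <- stats::sd(d)
    if (s == 0) stop("zero standard deviation; d is undefined")
    list(d = mean(d) / s, convention = "paired")
  } else {
    na <- length(baseline); nb <- length(treatment)
    sp <- sqrt(((na - 1) * stats::var(baseline) +
                (nb - 1) * stats::var(treatment)) / (na + nb - 2))
    if (sp == 0) stop("zero standard deviation; d is undefined")
    list(d = (mean(treatment) - mean(baseline)) / sp, convention = "pooled")
  }
}

#' Fold and percent change from baseline
#'
#' `fold = treatment / baseline` and
#' `percent = 100 * (treatment - baseline) / baseline`, so
#' `percent = 100 * (fold - 1)` identically.
#'
#' @param baseline,treatment numeric scalars or vectors; baseline must be
#'   strictly positive.
#' @return list with `fold` and `percent`.
#' @export
fold_percent_change <- function(baseline, treatment) {
  if (any(baseline <= 0)) stop("baseline must be > 0 for fold change")
  fold <- treatment / baseline
  list(fold = fold, percent = 100 * (fold - 1))
}

#' Full paired comparison record
#'
#' Bundles the paired t-test, paired Cohen's d and per-subject fold /
#' percent changes (computed on the raw scale) for one baseline-vs-treatment
#' comparison.
#'
#' @param baseline,treatment matched numeric vectors.
#' @param transform transform for the t-test (see [paired_t()]).
#' @param subject_ids optional subject labels.
#' @return list of class `PairedComparison`.
#' @export
paired_comparison <- function(baseline, treatment,
                              transform = c("none", "sqrt", "log"),
                              subject_ids = seq_along(baseline)) {
  transform <- match.arg(transform)
  tt <- paired_t(baseline, treatment, transform)
  dd <- cohens_d(baseline, treatment, paired = TRUE)
  fc <- fold_percent_change(baseline, treatment)
  structure(list(subject_ids = subject_ids,
                 baseline_values = baseline, treatment_values = treatment,
                 transform = transform,
                 t_statistic = tt$t_statistic, p_value = tt$p_value,
                 cohens_d = dd$d, d_convention = dd$convention,
                 mean_difference = mean(treatment) - mean(baseline),
                 mean_fold_change = mean(fc$fold),
                 mean_percent_change = mean(fc$percent)),
            class = "PairedComparison")
}

#' @export
print.PairedComparison <- function(x, ...) {
  cat(sprintf(
    "PairedComparison (n = %d, transform = %s)\n  t = %.3f, p = %.4g, Cohen's d (%s) = %.3f\n  mean difference = %.4g, mean fold = %.3f, mean %% change = %.1f%%\n",
    length(x$baseline_values), x$transform, x$t_statistic, x$p_value,
    x$d_convention, x$cohens_d, x$mean_difference, x$mean_fold_change,
    x$mean_percent_change))
  invisible(x)
}
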