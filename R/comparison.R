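## Cross-treatment concordance of TSS switching: equivalent/reversed
## segment sign patterns, Monte Carlo chance expectation and FDR-ventile
## trend.

#' Sign pattern of segment deltas
#'
#' Collapses per-segment deltas (percentage points) to a sign string over
#' (short, middle, long), with a dead zone: `|delta| < threshold` (and
#' absent segments) map to `0`.
#'
#' @param delta_short,delta_middle,delta_long Per-segment deltas
#'   (vectors, NA for absent segments).
#' @param threshold Dead-zone magnitude in percentage points (default 1;
#'   use the same value in both comparisons).
#' @return Character vector of patterns such as `"+0-"`.
#' @export
switch_pattern <- function(delta_short, delta_middle, delta_long,
                           threshold = 1) {
  one <- function(d) {
    s <- rep("0", length(d))
    s[!is.na(d) & d >= threshold] <- "+"
    s[!is.na(d) & d <= -threshold] <- "-"
    s
  }
  paste0(one(delta_short), one(delta_middle), one(delta_long))
}

#' Are two switching patterns equivalent?
#'
#' Equivalent means the sign matches in every segment (strict all-segment
#' rule).
#'
#' @param a,b Pattern strings from [switch_pattern()] (vectorized).
#' @return Logical vector.
#' @export
pattern_equivalence <- function(a, b) a == b

# flip every sign in a pattern string
flip_pattern <- function(p) chartr("+-", "-+", p)

#' Are two switching patterns reversed?
#'
#' Reversed means every nonzero sign is opposite and zero segments match,
#' i.e. `b` equals `a` with all signs flipped; an all-zero pattern is not
#' reversed (so equivalence and reversal are mutually exclusive for
#' patterns with at least one nonzero sign).
#'
#' @inheritParams pattern_equivalence
#' @return Logical vector.
#' @export
pattern_reversal <- function(a, b) {
  b == flip_pattern(a) & grepl("[+-]", a)
}

#' Monte Carlo estimate of chance pattern concordance
#'
#' Permutes the comparison-B patterns across transcripts and recomputes the
#' proportion of equivalent (or reversed) patterns each iteration,
#' estimating the concordance expected by chance when the two comparisons
#' share only their marginal category frequencies.
#'
#' @param patterns_a,patterns_b Pattern strings, one per transcript scored
#'   in both comparisons.
#' @param mode `"equivalent"` or `"reversed"`.
#' @param n_iter Permutations (default 10,000; below 100 a warning is
#'   issued).
#' @param seed Integer seed.
#' @return A list with `observed` (the unpermuted proportion), `chance`
#'   (Monte Carlo mean), `ci` (2.5/97.5 percentiles), `se` (Monte Carlo
#'   standard error of the mean) and `n_iter`.
#' @export
monte_carlo_chance <- function(patterns_a, patterns_b,
                               mode = c("equivalent", "reversed"),
                               n_iter = 10000L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(patterns_a) == length(patterns_b))
  if (n_iter < 100) warnf("n_iter < 100 gives an unstable chance estimate")
  if (length(unique(c(patterns_a, patterns_b))) < 2)
    warnf("fewer than two pattern categories present")
  fun <- if (mode == "equivalent") pattern_equivalence else pattern_reversal
  set.seed(as.integer(seed))
  stat <- vapply(seq_len(n_iter), function(i)
    mean(fun(patterns_a, sample(patterns_b))), numeric(1))
  list(observed = mean(fun(patterns_a, patterns_b)),
       chance = mean(stat),
       ci = stats::quantile(stat, c(0.025, 0.975), names = FALSE),
       se = stats::sd(stat) / sqrt(n_iter),
       n_iter = n_iter)
}

#' Concordance trend across FDR ventiles
#'
#' Bins transcripts into `bins` equal-count bins (ventiles by default) by
#' their comparison-A FDR and reports the per-bin proportion of
#' concordant (equivalent or reversed) switching versus comparison B,
#' with the slope of proportion against bin index from a linear fit.
#'
#' @param fdr Comparison-A FDR per transcript.
#' @param concordant Logical flags (equivalence or reversal vs comparison
#'   B) per transcript.
#' @param bins Number of equal-count bins (default 20).
#' @return A list with `table` (data.frame `bin`, `n`, `mean_fdr`,
#'   `proportion`), `slope`, `slope_se` and `slope_p`.
#' @export
ventile_trend <- function(fdr, concordant, bins = 20L) {
  stopifnot(length(fdr) == length(concordant))
  n <- length(fdr)
  if (n < bins) stopf("need at least %d transcripts for %d bins", bins, bins)
  ord <- order(fdr)
  bin <- ceiling(seq_len(n) / (n / bins))[order(ord)]  # equal-count +/- 1
  tab <- data.frame(bin = seq_len(bins))
  tab$n <- as.integer(table(factor(bin, levels = seq_len(bins))))
  tab$mean_fdr <- as.numeric(tapply(fdr, bin, mean))
  tab$proportion <- as.numeric(tapply(concordant, bin, mean))
  fit <- stats::lm(proportion ~ bin, data = tab)
  co <- summary(fit)$coefficients
  list(table = tab, slope = co["bin", "Estimate"],
       slope_se = co["bin", "Std. Error"],
       slope_p = co["bin", "Pr(>|t|)"])
}
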