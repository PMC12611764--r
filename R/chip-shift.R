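## Classification of positional shifts in histone-mark coverage around
## TSSs: trimmed cumulative-quantile positions, region filters, Wilcoxon
## directional and Kolmogorov-Smirnov non-directional tests with BH
## control.

#' Trimmed cumulative-quantile positions of a coverage profile
#'
#' Accumulates coverage 5' to 3' over the region, discards positions
#' beyond the point where 95% of the total signal is reached, then records
#' for each cumulative share q = 0.1%, 0.2%, ..., 100% of the trimmed
#' signal the first position whose cumulative share reaches q. The result
#' is a non-decreasing vector of 1,000 positions summarizing the signal
#' distribution; it is equivariant to translation of the profile and
#' invariant to coverage scaling.
#'
#' @param coverage Non-negative coverage per position.
#' @param positions Positions (nt relative to the TSS), same length,
#'   ascending.
#' @param trim Cumulative fraction beyond which positions are discarded
#'   (default 0.95).
#' @param n_quantiles Number of increments (default 1,000).
#' @return Numeric vector of `n_quantiles` positions; `NULL` when the
#'   region has zero signal.
#' @export
cumulative_quantile_positions <- function(coverage, positions,
                                          trim = 0.95,
                                          n_quantiles = 1000L) {
  stopifnot(length(coverage) == length(positions))
  if (any(coverage < 0)) stopf("coverage must be non-negative")
  total <- sum(coverage)
  if (total <= 0) return(NULL)
  cum <- cumsum(coverage)
  cut_idx <- which(cum >= trim * total)[1]
  coverage <- coverage[seq_len(cut_idx)]
  positions <- positions[seq_len(cut_idx)]
  cum <- cum[seq_len(cut_idx)]
  tt <- cum[cut_idx]
  q <- seq_len(n_quantiles) / n_quantiles * tt
  idx <- findInterval(q, cum, left.open = TRUE) + 1L
  idx[idx > cut_idx] <- cut_idx
  positions[idx]
}

#' Filter TSS regions by signal strength and background
#'
#' Coverage is first scaled onto a common 0-1-ish axis: both signal and
#' input control are divided by the 99th percentile of the positive
#' signal values across all regions, so typical strong signal maps near
#' 1 and background is judged relative to signal strength. A region is
#' retained when its maximum scaled signal is at least `min_signal`
#' (default 0.8) and its maximum scaled input-control coverage does not
#' exceed `max_background` (default 0.6; the signal bound is inclusive,
#' the background bound exclusive above). With no control the background
#' filter is skipped with a warning.
#'
#' @param signal Matrix regions x positions of library-normalized,
#'   replicate-mean coverage.
#' @param control Optional matching matrix of input-control coverage.
#' @param min_signal,max_background Thresholds on the scaled coverage.
#' @return Logical vector of retained regions.
#' @export
region_filters <- function(signal, control = NULL, min_signal = 0.8,
                           max_background = 0.6) {
  scale_of <- function(m) {
    pos <- m[m > 0]
    if (length(pos) == 0) return(1)
    stats::quantile(pos, 0.99, names = FALSE)
  }
  scale <- scale_of(signal)
  keep <- apply(signal, 1, max) / scale >= min_signal
  if (is.null(control)) {
    warnf("no input control supplied; background filter skipped")
  } else {
    keep <- keep & apply(control, 1, max) / scale <= max_background
  }
  keep
}

#' Directional shift test between two quantile-position profiles
#'
#' Two-sided Wilcoxon rank-sum test comparing the two 1,000-point
#' quantile-position vectors (replicate means), with direction assigned
#' from the B minus A position differences at the 25th, 50th and 75th
#' quantiles: `downstream` when all three are positive, `upstream` when
#' all negative, otherwise `other`.
#'
#' @param qa,qb Quantile-position vectors for conditions A and B.
#' @return A list with `p_value`, `direction` and `shifts` (named q25,
#'   q50, q75 differences in nt).
#' @export
directional_shift_test <- function(qa, qb) {
  stopifnot(length(qa) == length(qb))
  n <- length(qa)
  at <- round(c(0.25, 0.5, 0.75) * n)
  shifts <- stats::setNames(qb[at] - qa[at], c("q25", "q50", "q75"))
  direction <- if (all(shifts > 0)) "downstream"
    else if (all(shifts < 0)) "upstream" else "other"
  p <- if (identical(qa, qb)) 1 else
    stats::wilcox.test(qb, qa, exact = FALSE, correct = TRUE)$p.value
  list(p_value = p, direction = direction, shifts = shifts)
}

#' Non-directional distribution change test
#'
#' Two-sample Kolmogorov-Smirnov test on the quantile-position vectors.
#'
#' @inheritParams directional_shift_test
#' @return A list with `p_value` and the KS statistic `d`.
#' @export
distribution_change_test <- function(qa, qb) {
  if (identical(qa, qb)) return(list(p_value = 1, d = 0))
  kt <- suppressWarnings(stats::ks.test(qa, qb))
  list(p_value = kt$p.value, d = unname(kt$statistic))
}

#' Classify H3K4me3-style positional shifts across regions
#'
#' For each region, builds replicate-mean trimmed quantile-position
#' vectors per condition, runs the Wilcoxon directional and KS
#' non-directional tests, adjusts each test family with
#' Benjamini-Hochberg, and labels regions at `fdr < fdr_threshold`:
#' `downstream`/`upstream` for significant Wilcoxon tests with consistent
#' quartile signs, `other` for significant KS tests without a directional
#' call, else `unchanged`.
#'
#' @param coverage_a,coverage_b Arrays regions x positions x replicates of
#'   coverage for the two conditions (e.g. from
#'   [simulate_chip_coverage()]).
#' @param positions Position (nt) of each coverage column.
#' @param control Optional input-control matrix for [region_filters()];
#'   pass `NA` to skip filtering entirely.
#' @param fdr_threshold Significance threshold (default 0.01).
#' @param trim,n_quantiles Passed to [cumulative_quantile_positions()].
#' @return data.frame per retained region: `region`, `p_wilcoxon`, `p_ks`,
#'   `fdr_wilcoxon`, `fdr_ks`, `shift_q25/q50/q75`, `class`.
#' @export
classify_shift <- function(coverage_a, coverage_b, positions,
                           control = NULL, fdr_threshold = 0.01,
                           trim = 0.95, n_quantiles = 1000L) {
  stopifnot(length(dim(coverage_a)) == 3, length(dim(coverage_b)) == 3)
  n_regions <- dim(coverage_a)[1]

  mean_a <- apply(coverage_a, c(1, 2), mean)
  mean_b <- apply(coverage_b, c(1, 2), mean)
  # judge signal strength on the per-position maximum across conditions:
  # averaging conditions would dilute displaced bumps and bias the filter
  # against exactly the regions under test
  keep <- if (is.null(control) || !identical(control, NA)) {
    region_filters(pmax(mean_a, mean_b), control)
  } else rep(TRUE, n_regions)

  rep_mean_q <- function(arr, r) {
    qs <- lapply(seq_len(dim(arr)[3]), function(j)
      cumulative_quantile_positions(arr[r, , j], positions, trim,
                                    n_quantiles))
    qs <- qs[!vapply(qs, is.null, logical(1))]
    if (length(qs) == 0) return(NULL)
    Reduce(`+`, qs) / length(qs)
  }

  rows <- lapply(which(keep), function(r) {
    qa <- rep_mean_q(coverage_a, r)
    qb <- rep_mean_q(coverage_b, r)
    if (is.null(qa) || is.null(qb)) return(NULL)
    w <- directional_shift_test(qa, qb)
    k <- distribution_change_test(qa, qb)
    data.frame(region = r, p_wilcoxon = w$p_value, p_ks = k$p_value,
               shift_q25 = w$shifts["q25"], shift_q50 = w$shifts["q50"],
               shift_q75 = w$shifts["q75"], direction = w$direction,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stopf("no regions with signal after filtering")
  rownames(res) <- NULL
  res$fdr_wilcoxon <- bh_adjust(res$p_wilcoxon)
  res$fdr_ks <- bh_adjust(res$p_ks)
  res$class <- "unchanged"
  dir_call <- res$fdr_wilcoxon < fdr_threshold & res$direction != "other"
  res$class[dir_call] <- res$direction[dir_call]
  res$class[!dir_call & res$fdr_ks < fdr_threshold] <- "other"
  res
}
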