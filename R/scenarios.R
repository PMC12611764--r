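#' Scenario for simulating TSS peak count tables with planted switching
#'
#' Describes a synthetic experiment of multi-isoform transcripts whose 5'UTR
#' isoform proportions are drawn from a Dirichlet distribution, with a chosen
#' fraction of transcripts carrying a planted condition-dependent proportion
#' shift between their 5'-most and 3'-most isoforms. Replicate counts are
#' negative binomial around expected proportions, with unequal library sizes.
#'
#' @param n_transcripts Number of transcripts to simulate.
#' @param isoforms_per_transcript Integer range `c(min, max)` of isoforms
#'   (distinct TSS positions) per transcript.
#' @param utr_length_range Range (nt) from which the span of TSS positions
#'   upstream of the AUG is drawn.
#' @param baseline_conc Dirichlet concentration for baseline isoform
#'   proportions; larger values give more even proportions.
#' @param switch_fraction Fraction of transcripts with a planted switch.
#' @param switch_delta Proportion (of total transcript expression) moved
#'   between the 5'-most and 3'-most isoform in the treatment condition;
#'   must lie in (0, 1).
#' @param reps_per_condition Integer vector `c(control, treatment)` of
#'   replicates per condition; each must be >= 2.
#' @param mean_depth Expected number of tags per transcript per sample
#'   (before library-size scaling).
#' @param dispersion Negative-binomial size parameter; counts are
#'   `rnbinom(mu, size)`. Default 10 matches overdispersed CAGE tag counts.
#' @param lib_size_factors Optional per-sample library-size multipliers
#'   (length = total samples). Default draws factors uniformly in 0.5..1.5.
#' @param min_spacing Minimum spacing (nt) between TSS positions of one
#'   transcript, kept above the clustering window so isoforms stay distinct.
#' @param seed Integer seed; the simulator is deterministic given the seed.
#' @return An object of class `switch_scenario`.
#' @seealso [simulate_tss_counts()]
#' @export
switch_scenario <- function(n_transcripts = 1000,
                            isoforms_per_transcript = c(2L, 3L),
                            utr_length_range = c(60L, 300L),
                            baseline_conc = 5,
                            switch_fraction = 0.2,
                            switch_delta = 0.3,
                            reps_per_condition = c(3L, 3L),
                            mean_depth = 100,
                            dispersion = 10,
                            lib_size_factors = NULL,
                            min_spacing = 12L,
                            seed = 1L) {
  if (any(baseline_conc <= 0))
    stopf("baseline_conc must be positive (got %s)", baseline_conc[1])
  if (switch_fraction > 0 && (switch_delta <= 0 || switch_delta >= 1))
    stopf("switch_delta must lie in (0, 1)")
  if (length(reps_per_condition) != 2L || any(reps_per_condition < 2))
    stopf("reps_per_condition must give >= 2 replicates for both conditions")
  if (mean_depth < 0) stopf("mean_depth must be non-negative")
  n_samples <- sum(reps_per_condition)
  if (!is.null(lib_size_factors) && length(lib_size_factors) != n_samples)
    stopf("lib_size_factors must have length %d", n_samples)
  structure(
    list(n_transcripts = as.integer(n_transcripts),
         isoforms_per_transcript = as.integer(isoforms_per_transcript),
         utr_length_range = as.integer(utr_length_range),
         baseline_conc = baseline_conc,
         switch_fraction = switch_fraction,
         switch_delta = switch_delta,
         reps_per_condition = as.integer(reps_per_condition),
         mean_depth = mean_depth,
         dispersion = dispersion,
         lib_size_factors = lib_size_factors,
         min_spacing = as.integer(min_spacing),
         seed = as.integer(seed)),
    class = "switch_scenario")
}

#' Scenario for simulating histone-mark coverage around TSSs
#'
#' Each region carries a Gaussian coverage bump plus uniform background and
#' Poisson counting noise over a window anchored at the TSS (default
#' -2,000..+10,000 nt). A chosen number of regions have the bump centre
#' displaced by `planted_shift` nt in the treatment condition, and another
#' set have the bump symmetrically broadened with the centre fixed.
#'
#' @param n_regions Number of TSS regions.
#' @param region_span `c(lo, hi)` window in nt relative to the TSS.
#' @param peak_width Gaussian bump standard deviation (nt); must be > 0.
#' @param planted_shift Signed displacement (nt) of the bump centre in the
#'   treatment condition for shifted regions.
#' @param n_shifted,n_broadened Numbers of regions with a planted shift or a
#'   planted symmetric broadening (the remainder are null).
#' @param broaden_factor Multiplier on the bump SD for broadened regions.
#' @param background_level Fraction of expected signal that is uniform
#'   background; `1` gives pure background and no bump.
#' @param mean_depth Expected tags per region per replicate.
#' @param reps Replicates per condition.
#' @param bin_width Coverage bin size in nt. The default (10 nt) keeps a
#'   thousand-region scenario in memory; planted shifts of hundreds of nt
#'   are far above this resolution. Use 1 for single-nt checks.
#' @param seed Integer seed.
#' @return An object of class `coverage_scenario`.
#' @seealso [simulate_chip_coverage()]
#' @export
coverage_scenario <- function(n_regions = 200,
                              region_span = c(-2000L, 10000L),
                              peak_width = 300,
                              planted_shift = 500,
                              n_shifted = 0L,
                              n_broadened = 0L,
                              broaden_factor = 2,
                              background_level = 0.1,
                              mean_depth = 20000,
                              reps = 3L,
                              bin_width = 10L,
                              seed = 1L) {
  if (peak_width <= 0) stopf("peak_width must be > 0")
  if (background_level < 0 || background_level > 1)
    stopf("background_level must lie in [0, 1]")
  if (n_shifted + n_broadened > n_regions)
    stopf("n_shifted + n_broadened exceeds n_regions")
  structure(
    list(n_regions = as.integer(n_regions),
         region_span = as.integer(region_span),
         peak_width = peak_width,
         planted_shift = planted_shift,
         n_shifted = as.integer(n_shifted),
         n_broadened = as.integer(n_broadened),
         broaden_factor = broaden_factor,
         background_level = background_level,
         mean_depth = mean_depth,
         reps = as.integer(reps),
         bin_width = as.integer(bin_width),
         seed = as.integer(seed)),
    class = "coverage_scenario")
}

#' @export
print.switch_scenario <- function(x, ...) {
  cat("TSS switching scenario:", x$n_transcripts, "transcripts,",
      sprintf("%d-%d isoforms,", x$isoforms_per_transcript[1],
              x$isoforms_per_transcript[2]),
      sprintf("%.0f%% switched (delta %.2f),", 100 * x$switch_fraction,
              x$switch_delta),
      sprintf("%dv%d replicates, depth %g, seed %d\n",
              x$reps_per_condition[1], x$reps_per_condition[2],
              x$mean_depth, x$seed))
  invisible(x)
}

#' @export
print.coverage_scenario <- function(x, ...) {
  cat("TSS coverage scenario:", x$n_regions, "regions over",
      sprintf("[%d, %d] nt,", x$region_span[1], x$region_span[2]),
      x$n_shifted, "shifted,", x$n_broadened, "broadened, seed",
      x$seed, "\n")
  invisible(x)
}
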