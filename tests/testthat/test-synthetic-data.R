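# Synthetic-data generators: determinism, planted structure, degenerate
# inputs and truth-table consistency.

test_that("generators are deterministic given the seed", {
  sc <- switch_scenario(n_transcripts = 30, seed = 7)
  expect_identical(simulate_tss_counts(sc), simulate_tss_counts(sc))

  cc <- coverage_scenario(n_regions = 5, n_shifted = 2, reps = 2, seed = 7)
  expect_identical(simulate_chip_coverage(cc), simulate_chip_coverage(cc))

  expect_identical(
    simulate_feature_table(50, c(f = 0.5), seed = 7),
    simulate_feature_table(50, c(f = 0.5), seed = 7))
})

test_that("null switching scenario has empty truth and centred proportion differences", {
  sc <- switch_scenario(n_transcripts = 1000, switch_fraction = 0,
                        mean_depth = 200, seed = 21)
  sim <- simulate_tss_counts(sc)
  expect_false(any(sim$truth$switched))
  expect_true(all(sim$truth$delta == 0))

  # empirical per-isoform proportion difference between conditions
  ctrl <- sim$design$sample[sim$design$condition == "control"]
  trt <- sim$design$sample[sim$design$condition == "treatment"]
  pc <- rowSums(sim$counts[, ctrl])
  pt <- rowSums(sim$counts[, trt])
  prop_c <- pc / ave(pc, sim$counts$transcript_id, FUN = sum)
  prop_t <- pt / ave(pt, sim$counts$transcript_id, FUN = sum)
  d <- prop_t - prop_c
  d <- d[is.finite(d)]
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 3 * se)
})

test_that("planted switches move the stated proportion mass between extremes", {
  sc <- switch_scenario(n_transcripts = 400, switch_fraction = 0.5,
                        switch_delta = 0.3, mean_depth = 500, seed = 3)
  sim <- simulate_tss_counts(sc)
  sw <- sim$truth[sim$truth$switched, ]
  expect_true(all(sw$delta == 0.3))
  iso <- sim$isoforms
  moved <- abs(iso$prop_treatment - iso$prop_control)
  per_tx <- tapply(moved, iso$transcript_id, max)
  expect_equal(as.numeric(per_tx[sw$transcript_id]), rep(0.3, nrow(sw)),
               tolerance = 1e-12)
  # only the donor and acceptor isoforms move; middle isoforms untouched
  changed <- tapply(moved > 1e-12, iso$transcript_id, sum)
  expect_true(all(changed[sw$transcript_id] == 2))
  expect_true(all(changed[setdiff(names(changed), sw$transcript_id)] == 0))
})

test_that("zero depth yields a well-formed all-zero table", {
  sc <- switch_scenario(n_transcripts = 10, mean_depth = 0, seed = 1)
  sim <- simulate_tss_counts(sc)
  expect_true(all(sim$counts[, sim$design$sample] == 0))
  expect_true(all(c("transcript_id", "position") %in% names(sim$counts)))
  expect_equal(nrow(sim$design), 6)
})

test_that("invalid scenarios are rejected with informative messages", {
  expect_error(switch_scenario(baseline_conc = -1), "baseline_conc")
  expect_error(switch_scenario(reps_per_condition = c(1, 3)), "replicates")
  expect_error(switch_scenario(switch_delta = 1.2), "switch_delta")
  expect_error(coverage_scenario(peak_width = 0), "peak_width")
  expect_error(simulate_feature_table(10, c(f = 1), collinearity = 1),
               "collinearity")
  expect_error(simulate_feature_table(10, c(1, 2)), "named")
})

test_that("noiseless single coverage bump has cumulative median at its centre", {
  cc <- coverage_scenario(n_regions = 1, background_level = 0,
                          mean_depth = 5e6, peak_width = 200,
                          reps = 1, bin_width = 1, seed = 5)
  sim <- simulate_chip_coverage(cc)
  q <- cumulative_quantile_positions(sim$coverage$control[1, , 1],
                                     sim$offsets, trim = 1)
  expect_lt(abs(q[500] - sim$truth$centre[1]), 1.5)
})

test_that("pure-background regions fail the signal/background filters", {
  cc <- coverage_scenario(n_regions = 20, background_level = 1,
                          mean_depth = 2e4, reps = 2, seed = 8)
  sim <- simulate_chip_coverage(cc)
  sig <- apply(sim$coverage$control, c(1, 2), mean)
  keep <- region_filters(sig, sim$control_input)
  expect_true(all(!keep))
})

test_that("feature-table truth matches the analytic variance decomposition", {
  # noiseless single feature: univariate R^2 = 1
  ft <- simulate_feature_table(200, c(f = 1), noise_sd = 0, seed = 2)
  r2 <- suppressWarnings(summary(lm(ft$y ~ ft$X$f))$r.squared)
  expect_equal(r2, 1, tolerance = 1e-10)
  expect_equal(unname(ft$truth$unique_pct["f"]), 100)

  # two orthogonal features: planted unique variances sum to total R^2
  ft2 <- simulate_feature_table(100, c(a = 0.5, b = 0.3),
                                collinearity = 0, noise_sd = 1, seed = 2)
  expect_equal(sum(ft2$truth$unique_pct), ft2$truth$total_pct,
               tolerance = 1e-9)
  # and empirical R^2 approaches the planted total at large n
  ft3 <- simulate_feature_table(20000, c(a = 0.5, b = 0.3),
                                collinearity = 0, noise_sd = 1, seed = 3)
  r2 <- summary(lm(ft3$y ~ ft3$X$a + ft3$X$b))$r.squared
  expect_equal(100 * r2, ft3$truth$total_pct, tolerance = 0.15)
})

test_that("TPM-based statistics are invariant to library-size scaling", {
  sc <- switch_scenario(n_transcripts = 40, switch_fraction = 0.3,
                        mean_depth = 300, seed = 13)
  sim <- simulate_tss_counts(sc)
  scaled <- sim$counts
  scaled[["ctrl_1"]] <- scaled[["ctrl_1"]] * 7
  s1 <- score_tss_switching(normalize_tpm(sim$counts, sim$design),
                            sim$design, "treatment", "control")
  s2 <- score_tss_switching(normalize_tpm(scaled, sim$design),
                            sim$design, "treatment", "control")
  expect_equal(s1, s2, tolerance = 1e-12)
})
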