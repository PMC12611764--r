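# Three-arm switching test: routing, the moderated interaction model,
# the Fisher arm, the unique-isoform probability and BH pooling.

make_iso <- function(det_a, det_b, design, value = 5) {
  # one isoform with the requested per-replicate detection pattern plus a
  # fully detected companion isoform
  n <- nrow(design)
  row1 <- ifelse(c(seq_len(sum(design$condition == design$condition[1])) <= det_a,
                   seq_len(sum(design$condition != design$condition[1])) <= det_b),
                 value, 0)
  iso <- data.frame(transcript_id = "tx", isoform_id = c("i1", "i2"),
                    rbind(row1, rep(value, n)),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(iso)[-(1:2)] <- design$sample
  iso
}

test_that("isoforms are routed to quantitative, fisher, unique or untestable", {
  d32 <- make_design(3, 2)
  expect_equal(route_isoforms(make_iso(3, 2, d32), d32)$arm[1], "quantitative")
  expect_equal(route_isoforms(make_iso(2, 2, d32), d32)$arm[1], "fisher")
  expect_equal(route_isoforms(make_iso(2, 0, d32), d32)$arm[1], "unique")
  expect_equal(route_isoforms(make_iso(1, 0, d32), d32)$arm[1], "unique")
  expect_equal(route_isoforms(make_iso(1, 2, d32), d32)$arm[1], "untestable")

  d3 <- rbind(make_design(2, 2), data.frame(sample = "c1", condition = "third",
                                            replicate = "1"))
  iso <- make_iso(2, 2, make_design(2, 2))
  iso$c1 <- 1
  expect_error(route_isoforms(iso, d3), "conditions")
})

test_that("interaction test returns p near 1 for identical noiseless proportions", {
  design <- make_design(3, 3)
  iso <- data.frame(transcript_id = "tx", isoform_id = c("i1", "i2"),
                    rbind(rep(600, 6), rep(400, 6)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(iso)[-(1:2)] <- design$sample
  qt <- quant_interaction_test(iso, design, min_rvm = Inf)
  expect_gt(qt$p_value, 0.99)
  expect_lt(qt$f_stat, 1e-10)
})

test_that("interaction test is invariant to isoform relabelling", {
  sc <- switch_scenario(n_transcripts = 60, switch_fraction = 0.3, seed = 17)
  sim <- simulate_tss_counts(sc)
  iso <- sim$counts
  names(iso)[names(iso) == "position"] <- "isoform_id"
  a <- quant_interaction_test(iso, sim$design)
  # reverse isoform order within transcripts (relabel)
  iso2 <- iso[order(iso$transcript_id, -as.numeric(iso$isoform_id)), ]
  b <- quant_interaction_test(iso2, sim$design)
  expect_equal(a$p_value, b$p_value[match(a$transcript_id, b$transcript_id)],
               tolerance = 1e-9)
})

test_that("RVM shrinkage has the correct closed-form limits", {
  s2 <- c(0.5, 2, 8); m <- 4; prior <- 1.5
  # large a at fixed prior mean: shrunken variance -> prior mean
  a_big <- 1e8
  fit_big <- list(a = a_big, b = 1 / (a_big * prior))
  expect_equal(rvm_shrink(s2, m, fit_big), rep(prior, 3), tolerance = 1e-6)
  # small a at fixed prior mean: shrunken variance -> observed variance
  a_small <- 1e-8
  fit_small <- list(a = a_small, b = 1 / (a_small * prior))
  expect_equal(rvm_shrink(s2, m, fit_small), s2, tolerance = 1e-6)
})

test_that("RVM maximum likelihood recovers hyperparameters from scaled-F draws", {
  set.seed(4)
  a_true <- 3; b_true <- 0.8; m <- 6
  s2 <- rf(4000, m, 2 * a_true) / (a_true * b_true)
  fit <- rvm_fit(s2, m)
  expect_equal(fit$a, a_true, tolerance = 0.25)
  expect_equal(fit$b, b_true, tolerance = 0.25)
})

test_that("fisher arm matches the printed example and handles degenerate margins", {
  design <- make_design(2, 2)
  iso <- data.frame(transcript_id = "tx", isoform_id = c("i1", "i2"),
                    a1 = c(5, 0), a2 = c(5, 0), b1 = c(0, 5), b2 = c(0, 5),
                    stringsAsFactors = FALSE)
  ft <- fisher_arm(iso, design)
  expect_equal(ft$p_value[1], 2 / choose(20, 10), tolerance = 1e-12)

  flat <- iso
  flat[, design$sample] <- 5
  expect_equal(fisher_arm(flat, design)$p_value, c(1, 1))

  zero <- iso
  zero[, c("a1", "a2")] <- 0
  expect_equal(fisher_arm(zero, design)$p_value[1], 1)
})

test_that("unique-isoform probability reproduces the closed formula", {
  expect_equal(unique_isoform_probability(90, 10, 10), 0.9^10)
  expect_equal(unique_isoform_probability(50, 1, 0), 1)
  expect_equal(unique_isoform_probability(0, 10, 3), 0)
  expect_equal(unique_isoform_probability(0, 10, 0), 1)
  expect_error(unique_isoform_probability(5, 0, 1), "r_ui")
  expect_error(unique_isoform_probability(-1, 2, 1), ">= 0")
  # monotone non-increasing in r_sj and in r_ui
  p_sj <- unique_isoform_probability(20, 5, 0:30)
  expect_true(all(diff(p_sj) <= 0))
  p_ui <- unique_isoform_probability(20, 1:30, 10)
  expect_true(all(diff(p_ui) <= 0))
})

test_that("BH adjustment matches hand computation and validates input", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_fdr(c(0.005, 0.009, 0.05)),
               c(0.0135, 0.0135, 0.05))  # 3*0.005/1 vs 3*0.009/2
  expect_error(adjust_fdr(c(0.5, 1.2)), "p-values")
})

test_that("three-arm wrapper pools arms and reports significant transcripts", {
  sc <- switch_scenario(n_transcripts = 120, switch_fraction = 0.25,
                        mean_depth = 150, seed = 31)
  sim <- simulate_tss_counts(sc)
  q <- quantify_tss(sim$counts, sim$design)
  ts <- test_tss_switching(q$isoforms_counts, sim$design)
  expect_s3_class(ts, "tss_switch_test")
  expect_true(all(ts$results$fdr >= 0 & ts$results$fdr <= 1))
  expect_true(all(ts$results$arm %in% c("quantitative", "fisher", "unique")))
  sig <- significant_transcripts(ts)
  truth_sw <- sim$truth$transcript_id[sim$truth$switched]
  expect_gt(mean(truth_sw %in% sig), 0.5)
  expect_output(print(ts), "three-arm")
  expect_output(print(summary(ts)), "Significant")
})
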