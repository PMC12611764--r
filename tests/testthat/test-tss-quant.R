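# Peak filtering, TPM normalization, sliding-window clustering and the
# saturation curve.

test_that("reproducibility filter applies the n-1 and all-replicates rules", {
  design <- make_design(3, 2)
  # peak detected in 2 of 3 control replicates, absent from treatment
  counts <- make_peaks("tx1", c(10L, 20L),
                       rbind(c(5, 5, 0, 0, 0), c(9, 9, 9, 9, 9)), design)
  len <- filter_reproducible_peaks(counts, design, "lenient", min_reads = 0)
  expect_true(10 %in% len$position)
  strict <- filter_reproducible_peaks(counts, design, "strict", min_reads = 0)
  expect_false(10 %in% strict$position)
  expect_true(20 %in% strict$position)  # all 5 samples
  expect_error(filter_reproducible_peaks(counts, design, "bogus"))
})

test_that("transcripts with fewer than ten reads are removed entirely", {
  design <- make_design(2, 2)
  counts <- rbind(
    make_peaks("tx1", c(5L, 9L), rbind(c(2, 2, 1, 1), c(1, 1, 0, 1)), design),
    make_peaks("tx2", 7L, matrix(c(5, 5, 5, 5), 1), design))
  out <- filter_reproducible_peaks(counts, design, "lenient")
  expect_false("tx1" %in% out$transcript_id)  # 9 reads total
  expect_true("tx2" %in% out$transcript_id)   # 20 reads
})

test_that("TPM normalization scales samples to one million and is scale invariant", {
  design <- make_design(2, 2)
  counts <- make_peaks("tx1", c(1L, 2L),
                       rbind(c(3, 1, 1, 2), c(1, 1, 1, 2)), design)
  tpm <- normalize_tpm(counts, design)
  expect_equal(tpm$a1, c(7.5e5, 2.5e5))
  expect_equal(unname(colSums(tpm[, design$sample])), rep(1e6, 4))
  scaled <- counts
  scaled$a1 <- scaled$a1 * 7
  expect_equal(normalize_tpm(scaled, design), tpm)
  zero <- counts; zero$a2 <- 0
  expect_error(normalize_tpm(zero, design), "a2")
})

test_that("low-expression peaks are removed below 25% of the transcript mean", {
  design <- make_design(2, 2)
  tab <- function(m1, m2)
    make_peaks("tx", c(1L, 2L), rbind(rep(m1, 4), rep(m2, 4)), design)
  expect_equal(nrow(filter_low_expression_peaks(tab(100, 20), design)), 2)
  kept <- filter_low_expression_peaks(tab(100, 10), design)
  expect_equal(kept$position, 1L)  # threshold 13.75 removes the 10
  all_equal <- filter_low_expression_peaks(tab(100, 100), design)
  expect_equal(nrow(all_equal), 2)
})

test_that("sliding-window clustering follows the chain rule and dynamic window", {
  pk <- data.frame(transcript_id = "t", position = c(10L, 12L, 14L, 30L),
                   s1 = 1)
  cl <- cluster_tss(pk)
  expect_equal(cl$lo, c(10L, 30L))
  expect_equal(cl$hi, c(15L, 31L))

  single <- cluster_tss(data.frame(transcript_id = "t", position = 42L, s1 = 1))
  expect_equal(nrow(single), 1)
  expect_equal(c(single$lo, single$hi), c(42L, 43L))

  expect_equal(dynamic_window(100), 5L)
  expect_equal(dynamic_window(400), 10L)  # ceil(0.025 * 400)
  expect_equal(dynamic_window(201), 6L)   # ceiling applies

  # chaining from the last included peak, not the cluster start
  chain <- cluster_tss(data.frame(transcript_id = "t",
                                  position = c(1L, 5L, 9L, 13L), s1 = 1))
  expect_equal(nrow(chain), 1)

  # order independence and idempotence
  shuf <- pk[c(3, 1, 4, 2), ]
  expect_equal(cluster_tss(shuf), cl)
})

test_that("cluster unification merges overlapping and abutting intervals", {
  mk <- function(lo, hi) data.frame(transcript_id = "t",
                                    cluster_id = paste0("c", seq_along(lo)),
                                    lo = lo, hi = hi)
  u <- unify_clusters(mk(10L, 15L), mk(12L, 21L))
  expect_equal(c(u$lo, u$hi), c(10L, 21L))
  expect_equal(unify_clusters(u, u)[, c("lo", "hi")], u[, c("lo", "hi")])
  v <- unify_clusters(mk(c(10L, 30L), c(15L, 32L)), mk(50L, 51L))
  expect_equal(nrow(v), 3)
})

test_that("cluster quantification conserves total transcript expression", {
  sc <- switch_scenario(n_transcripts = 25, seed = 5)
  sim <- simulate_tss_counts(sc)
  q <- quantify_tss(sim$counts, sim$design)
  for (s in sim$design$sample) {
    peak_tot <- tapply(q$peaks_tpm[[s]], q$peaks_tpm$transcript_id, sum)
    iso_tot <- tapply(q$isoforms_tpm[[s]], q$isoforms_tpm$transcript_id, sum)
    expect_equal(iso_tot[names(peak_tot)], peak_tot, tolerance = 1e-9)
  }
})

test_that("filters commute with replicate relabelling within a condition", {
  sc <- switch_scenario(n_transcripts = 30, seed = 9)
  sim <- simulate_tss_counts(sc)
  relabel <- sim$design
  relabel$replicate[relabel$condition == "control"] <-
    rev(relabel$replicate[relabel$condition == "control"])
  a <- filter_reproducible_peaks(sim$counts, sim$design)
  b <- filter_reproducible_peaks(sim$counts, relabel)
  expect_identical(a, b)
})

test_that("saturation curve is monotone and reaches the full peak count", {
  sc <- switch_scenario(n_transcripts = 100, mean_depth = 5000, seed = 2)
  sim <- simulate_tss_counts(sc)
  cur <- saturation_curve(sim$counts, increment = 2e5, seed = 1)
  expect_true(all(diff(cur$unique_peaks) >= 0))
  expect_true(all(diff(cur$transcripts) >= 0))
  sc_cols <- sim$design$sample
  full_peaks <- sum(rowSums(sim$counts[, sc_cols]) > 1)
  expect_equal(cur$unique_peaks[nrow(cur)], full_peaks)
  expect_error(saturation_curve(sim$counts, increment = 1e9), "increment")
})
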