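# Cumulative expression differences, segment-neighbourhood change points,
# per-segment enrichment, TSS-switch score and categories.

test_that("cumulative difference is zero for identical distributions and at the end", {
  design <- make_design(2, 2)
  counts <- make_peaks("tx", c(10L, 50L, 90L),
                       matrix(rep(c(2, 3, 5), 4), ncol = 4), design)
  tpm <- normalize_tpm(counts, design)
  prof <- cumulative_difference(tpm, design, "treatment", "control")
  expect_equal(prof$diff, rep(0, 3))

  set.seed(1)
  rnd <- make_peaks("tx", c(1L, 7L, 30L, 44L),
                    matrix(rpois(16, 20) + 1, ncol = 4), design)
  prof2 <- cumulative_difference(normalize_tpm(rnd, design), design,
                                 "treatment", "control")
  expect_equal(prof2$diff[nrow(prof2)], 0, tolerance = 1e-12)
})

test_that("opposed point masses give a unit difference between their positions", {
  design <- make_design(2, 2)
  # all treatment mass at position 10, all control mass at position 90
  counts <- make_peaks("tx", c(10L, 90L),
                       rbind(c(0, 0, 8, 8), c(4, 4, 0, 0)), design)
  # normalize_tpm would fail on all-zero columns of a single transcript;
  # cumulative_difference accepts any expression units, so use raw means
  prof <- cumulative_difference(counts, design, "treatment", "control")
  expect_equal(prof$diff, c(1, 0))

  # a zero-expression condition is skipped with a report
  zero <- make_peaks("tx", c(10L, 90L), rbind(c(0, 0, 8, 8), c(0, 0, 1, 1)),
                     design)
  prof0 <- cumulative_difference(zero, design, "treatment", "control")
  expect_equal(nrow(prof0), 0)
  expect_equal(attr(prof0, "skipped"), "tx")
})

test_that("change-point detection matches the printed traces", {
  expect_equal(detect_changepoints(c(5, 5, 5, 1, 1)), 3L)
  expect_equal(detect_changepoints(c(0, 0, 4, 4, 0, 0)), c(2L, 4L))
  expect_equal(detect_changepoints(rep(2, 10)), integer())
  expect_equal(detect_changepoints(numeric()), integer())
})

test_that("segment-neighbourhood DP equals brute-force enumeration", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(5:25, 1)
    # half structured (segment means), half pure noise
    x <- rnorm(n, sd = 0.5)
    if (i %% 2 == 0) {
      b <- sort(sample(seq_len(n - 1), 2))
      x <- x + rep(rnorm(3, sd = 2), times = diff(c(0, b, n)))
    }
    expect_identical(detect_changepoints(x), brute_changepoints(x))
  }
})

test_that("segment enrichment matches direct arithmetic and conserves mass", {
  design <- make_design(2, 2)
  # treatment shares {short 0.8, long 0.2}; control {0.6, 0.4}
  prof <- data.frame(transcript_id = "tx", position = c(10L, 80L),
                     mean_treat = c(0.8, 0.2), mean_ctrl = c(0.6, 0.4))
  se <- segment_enrichment(prof, 1L)
  expect_equal(unname(se$delta), c(20, -20))
  expect_equal(names(se$delta), c("short", "long"))
  expect_equal(se$changepoint_positions, 80L)

  set.seed(3)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    prof <- data.frame(transcript_id = "t", position = sort(sample(1:200, n)),
                       mean_treat = runif(n), mean_ctrl = runif(n))
    cp <- sort(sample(seq_len(n - 1), sample(0:2, 1)))
    se <- segment_enrichment(prof, cp)
    expect_lt(abs(sum(se$delta)), 1e-9)
  }
})

test_that("TSS-switch score is the delta range by default", {
  expect_equal(tss_switch_score(c(short = 20, long = -20)), 40)
  expect_equal(tss_switch_score(c(short = 25, middle = 5, long = -30)), 55)
  expect_equal(tss_switch_score(c(short = 0, middle = 0, long = 0)), 0)
  expect_equal(tss_switch_score(c(short = 25, middle = 5, long = -30),
                                mode = "maxabs"), 30)
})

test_that("category labels follow the enriched-segment rule", {
  expect_equal(classify_category(c(short = 20, middle = 0, long = -20)),
               "short")
  expect_equal(classify_category(c(short = -20, middle = 0, long = 20)),
               "long")
  expect_equal(classify_category(c(short = 10, middle = -20, long = 10)),
               "short+long")
  expect_equal(classify_category(c(short = 0.5, middle = 0, long = -0.5)),
               "none")
})

test_that("scores are invariant under uniform expression scaling", {
  sc <- switch_scenario(n_transcripts = 30, switch_fraction = 0.5, seed = 23)
  sim <- simulate_tss_counts(sc)
  tpm <- normalize_tpm(sim$counts, sim$design)
  s1 <- score_tss_switching(tpm, sim$design, "treatment", "control")
  tpm2 <- tpm
  tpm2[, sim$design$sample] <- tpm2[, sim$design$sample] * 1234
  s2 <- score_tss_switching(tpm2, sim$design, "treatment", "control")
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("two-position transcripts fall back to a single boundary", {
  design <- make_design(2, 2)
  counts <- make_peaks("tx", c(10L, 60L),
                       rbind(c(8, 8, 2, 2), c(2, 2, 8, 8)), design)
  s <- score_tss_switching(counts, design, "treatment", "control")
  expect_equal(s$cp1, 60L)
  expect_equal(s$delta_short, -60)
  expect_equal(s$delta_long, 60)
  expect_equal(s$category, "long")
})
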