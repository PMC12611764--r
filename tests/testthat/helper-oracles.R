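# Independent brute-force oracles and small fixture builders used across
# the suite. Each oracle is deliberately written as plain enumeration,
# independent of the package code paths it checks.

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins: sum of probabilities of tables no more
# likely than the observed one (with the usual relative tolerance for
# floating-point equality of probabilities).
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  amin <- max(0, c1 - r2); amax <- min(r1, c1)
  dens <- stats::dhyper(amin:amax, r1, r2, c1)
  sum(dens[dens <= dens[a - amin + 1] * (1 + 1e-7)])
}

# Minimal within-segment sum of squares over all partitions of x into
# exactly k contiguous segments, by explicit enumeration of boundaries.
brute_best_partition <- function(x, k) {
  n <- length(x)
  seg_sse <- function(i, j) { s <- x[i:j]; sum((s - mean(s))^2) }
  if (k == 1) return(list(cost = seg_sse(1, n), breaks = integer()))
  combs <- utils::combn(n - 1, k - 1)
  best <- Inf; best_br <- NULL
  for (i in seq_len(ncol(combs))) {
    br <- combs[, i]
    bounds <- c(0, br, n)
    cost <- sum(vapply(seq_len(k), function(s)
      seg_sse(bounds[s] + 1, bounds[s + 1]), numeric(1)))
    if (cost < best) { best <- cost; best_br <- br }
  }
  list(cost = best, breaks = best_br)
}

# Change points by brute force: best partition per k = 1..3, then the same
# AIC rule (pooled-variance Gaussian cost, penalty 2 per change point).
brute_changepoints <- function(x, kmax = 3) {
  sigma2 <- mean((x - mean(x))^2)
  if (sigma2 == 0) return(integer())
  kmax <- min(kmax, length(x))
  parts <- lapply(seq_len(kmax), function(k) brute_best_partition(x, k))
  aic <- vapply(seq_len(kmax), function(k)
    parts[[k]]$cost / sigma2 + 2 * (k - 1), numeric(1))
  parts[[which.min(aic)]]$breaks
}

# uORF count by a position-list scan: AUG occurrences and in-frame stop
# occurrences matched over explicit index arithmetic.
brute_uorfs <- function(seq) {
  s <- toupper(gsub("T", "U", toupper(seq)))
  starts <- gregexpr("AUG", s, fixed = TRUE)[[1]]
  if (starts[1] == -1) return(0L)
  stop_pos <- sort(unique(unlist(lapply(c("UAA", "UAG", "UGA"), function(sc) {
    p <- gregexpr(sc, s, fixed = TRUE)[[1]]
    p[p > 0]
  }))))
  n <- nchar(s)
  sum(vapply(starts, function(i)
    any(stop_pos >= i + 3 & (stop_pos - i) %% 3 == 0 & stop_pos + 2 <= n),
    logical(1)))
}

# KS statistic as the explicit sup-difference of empirical CDFs over the
# pooled support.
brute_ks_d <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(vapply(grid, function(g) mean(x <= g) - mean(y <= g), numeric(1))))
}

# Rank-sum statistic W as the explicit count of pairs (x_i > y_j) plus
# half-ties (the Mann-Whitney U for the first sample).
brute_rank_sum_w <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# A tiny two-condition design.
make_design <- function(n_a = 3, n_b = 3, conditions = c("control", "treatment")) {
  data.frame(
    sample = c(paste0("a", seq_len(n_a)), paste0("b", seq_len(n_b))),
    condition = rep(conditions, c(n_a, n_b)),
    replicate = c(seq_len(n_a), seq_len(n_b)),
    stringsAsFactors = FALSE)
}

# A peak table from a matrix of counts (rows = positions).
make_peaks <- function(transcript_id, positions, counts, design) {
  stopifnot(nrow(counts) == length(positions))
  colnames(counts) <- design$sample
  data.frame(transcript_id = transcript_id, position = positions, counts,
             stringsAsFactors = FALSE, check.names = FALSE)
}
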