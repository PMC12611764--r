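## Change-point segmentation of cumulative 5'UTR expression differences,
## per-segment enrichment and the TSS-switch score.

#' Cumulative expression difference between conditions
#'
#' Per transcript, peak (or cluster) expression is averaged over replicates
#' within each condition, accumulated over positions in ascending
#' nt-upstream-of-AUG order (from the AUG outward) and normalized to a
#' cumulative share in `[0, 1]`. The difference (treatment minus control)
#' is zero at the last position by construction.
#'
#' @param tpm Peak TPM table (`transcript_id`, `position`, sample columns).
#' @param design Design table.
#' @param treatment,control Condition labels in `design$condition`.
#' @return data.frame `transcript_id`, `position`, `mean_treat`,
#'   `mean_ctrl` (replicate-mean TPM), `cum_treat`, `cum_ctrl` (cumulative
#'   shares) and `diff`. Transcripts with zero total expression in either
#'   condition are skipped; their ids are in attribute `"skipped"`.
#' @export
cumulative_difference <- function(tpm, design, treatment, control) {
  design <- check_design(design, tpm)
  st <- design$sample[design$condition == treatment]
  sx <- design$sample[design$condition == control]
  if (length(st) == 0 || length(sx) == 0)
    stopf("conditions '%s'/'%s' not found in design", treatment, control)
  tpm <- tpm[order(tpm$transcript_id, tpm$position), , drop = FALSE]
  mt <- rowMeans(tpm[, st, drop = FALSE])
  mc <- rowMeans(tpm[, sx, drop = FALSE])
  tot_t <- stats::ave(mt, tpm$transcript_id, FUN = sum)
  tot_c <- stats::ave(mc, tpm$transcript_id, FUN = sum)
  bad <- tot_t == 0 | tot_c == 0
  skipped <- unique(tpm$transcript_id[bad])
  keep <- !bad
  out <- data.frame(transcript_id = tpm$transcript_id[keep],
                    position = tpm$position[keep],
                    mean_treat = mt[keep], mean_ctrl = mc[keep],
                    stringsAsFactors = FALSE)
  out$cum_treat <- stats::ave(mt[keep] / tot_t[keep], out$transcript_id,
                              FUN = cumsum)
  out$cum_ctrl <- stats::ave(mc[keep] / tot_c[keep], out$transcript_id,
                             FUN = cumsum)
  out$diff <- out$cum_treat - out$cum_ctrl
  attr(out, "skipped") <- skipped
  out
}

# Exact segment-neighbourhood dynamic programme: minimal within-segment sum
# of squares for 1..kmax segments. Returns, per k, the optimal cost and the
# last-point indices of the first k-1 segments.
segneigh_sse <- function(x, kmax = 3L) {
  n <- length(x)
  kmax <- min(kmax, n)
  cx <- c(0, cumsum(x))
  cx2 <- c(0, cumsum(x^2))
  sse <- function(i, j)  # cost of segment x[i..j]
    cx2[j + 1] - cx2[i] - (cx[j + 1] - cx[i])^2 / (j - i + 1)
  # cost[i, j]: segment i..j; precompute on demand via closures is fine at
  # the n encountered here (vectors are per-transcript TSS positions)
  C <- matrix(Inf, kmax, n)   # C[k, j] = min cost of x[1..j] in k segments
  B <- matrix(0L, kmax, n)    # argmin split point
  for (j in seq_len(n)) C[1, j] <- sse(1, j)
  if (kmax >= 2) {
    for (k in 2:kmax) {
      for (j in k:n) {
        splits <- (k - 1):(j - 1)
        costs <- vapply(splits, function(m)
          C[k - 1, m] + sse(m + 1, j), numeric(1))
        best <- which.min(costs)
        C[k, j] <- costs[best]
        B[k, j] <- splits[best]
      }
    }
  }
  backtrack <- function(k) {
    if (k == 1) return(integer())
    ends <- integer(k - 1)
    j <- n
    for (kk in k:2) {
      ends[kk - 1] <- B[kk, j]
      j <- B[kk, j]
    }
    ends
  }
  list(cost = C[, n], breaks = lapply(seq_len(kmax), backtrack))
}

#' Detect up to two change points in a difference vector
#'
#' Exact segment-neighbourhood search minimizing the within-segment sum of
#' squared deviations from segment means, for 1 to `max_cp + 1` segments.
#' The number of segments is chosen by AIC under a Gaussian mean-change
#' likelihood with the variance pooled over the whole vector, charging a
#' penalty of 2 per change point on the -2 log-likelihood scale. A
#' constant vector yields no change points.
#'
#' @param x Numeric vector (typically the cumulative expression
#'   difference evaluated at each TSS position).
#' @param max_cp Maximum number of change points (default 2, i.e. at most
#'   three segments).
#' @return Integer vector of change-point indices: `i` means the mean
#'   changes between `x[i]` and `x[i + 1]`. Length 0 to `max_cp`.
#' @export
detect_changepoints <- function(x, max_cp = 2L) {
  n <- length(x)
  if (n < 2) return(integer())
  sigma2 <- mean((x - mean(x))^2)
  if (sigma2 == 0) return(integer())
  kmax <- min(max_cp + 1L, n)
  dp <- segneigh_sse(x, kmax)
  aic <- dp$cost / sigma2 + 2 * (seq_len(kmax) - 1)
  k <- which.min(aic)
  dp$breaks[[k]]
}

#' Per-segment enrichment from TSS switching
#'
#' Segments the transcript's positions at the detected change points and
#' quantifies, per segment, the difference in the proportion of total TSS
#' expression between treatment and control, in percentage points. Deltas
#' sum to zero. Segment labels follow the distance from the AUG: `short`
#' is the segment nearest the start codon, then `middle` and `long` (with
#' one change point only `short` and `long` exist; with none, `all`).
#'
#' @param profile One transcript's rows from [cumulative_difference()].
#' @param changepoints Indices from [detect_changepoints()] on
#'   `profile$diff`.
#' @return A list with `changepoint_positions` (nt: first position of each
#'   new segment), `segments` (data.frame `segment`, `lo`, `hi`, `delta`)
#'   and named `delta` vector (percentage points, treatment - control).
#' @export
segment_enrichment <- function(profile, changepoints) {
  stopifnot(nrow(profile) >= 1)
  ord <- order(profile$position)
  profile <- profile[ord, , drop = FALSE]
  n <- nrow(profile)
  cp <- sort(changepoints)
  bounds <- c(0L, cp, n)
  k <- length(bounds) - 1L
  labels <- switch(as.character(k), "1" = "all", "2" = c("short", "long"),
                   c("short", "middle", "long"))
  pt <- profile$mean_treat / sum(profile$mean_treat)
  pc <- profile$mean_ctrl / sum(profile$mean_ctrl)
  seg <- lapply(seq_len(k), function(i) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    data.frame(segment = labels[i],
               lo = if (i == 1) 0L else profile$position[bounds[i] + 1L],
               hi = if (i == k) max(profile$position) + 1L else
                 profile$position[bounds[i + 1L] + 1L],
               delta = 100 * (sum(pt[idx]) - sum(pc[idx])),
               stringsAsFactors = FALSE)
  })
  seg <- do.call(rbind, seg)
  delta <- stats::setNames(seg$delta, seg$segment)
  list(changepoint_positions = if (length(cp) > 0)
         profile$position[cp + 1L] else integer(),
       segments = seg, delta = delta)
}

#' TSS-switch score
#'
#' Summarizes 5'UTR remodelling as the spread of per-segment enrichment
#' differences: by default the range `max(delta) - min(delta)` across
#' segments (with two segments of +/-d this is ~2d), or the maximum
#' absolute delta with `mode = "maxabs"`. In percentage points; invariant
#' under uniform scaling of expression.
#'
#' @param delta Named vector of per-segment deltas (percentage points).
#' @param mode `"range"` (default) or `"maxabs"`.
#' @return Non-negative score.
#' @export
tss_switch_score <- function(delta, mode = c("range", "maxabs")) {
  mode <- match.arg(mode)
  delta <- delta[!is.na(delta)]
  if (length(delta) == 0) return(0)
  if (mode == "range") max(delta) - min(delta) else max(abs(delta))
}

#' Categorize which 5'UTR segments are enriched
#'
#' Labels a transcript by the subset of segments whose delta exceeds the
#' threshold (enriched under treatment), joined with `+`; `none` when no
#' segment passes.
#'
#' @param delta Named per-segment deltas (percentage points).
#' @param threshold Minimum magnitude in percentage points (default 1).
#' @return Category string such as `"short"`, `"long"`, `"short+long"`,
#'   `"middle"` or `"none"`.
#' @export
classify_category <- function(delta, threshold = 1) {
  up <- names(delta)[!is.na(delta) & delta > threshold]
  up <- up[up != "all"]
  if (length(up) == 0) "none" else paste(up, collapse = "+")
}

#' Score TSS switching for a set of transcripts
#'
#' Runs [cumulative_difference()], [detect_changepoints()],
#' [segment_enrichment()], [tss_switch_score()] and [classify_category()]
#' per transcript. With fewer than three positions the change-point search
#' is skipped and the single boundary is placed before the second position.
#'
#' @inheritParams cumulative_difference
#' @param transcripts Optional subset of transcript ids (e.g. the
#'   significant switchers from [test_tss_switching()]); default all.
#' @param score_mode Passed to [tss_switch_score()].
#' @param threshold Passed to [classify_category()] (percentage points).
#' @return data.frame `transcript_id`, `cp1`, `cp2` (nt, NA when absent),
#'   `delta_short`, `delta_middle`, `delta_long` (NA when the segment does
#'   not exist), `score`, `category`.
#' @export
score_tss_switching <- function(tpm, design, treatment, control,
                                transcripts = NULL,
                                score_mode = c("range", "maxabs"),
                                threshold = 1) {
  score_mode <- match.arg(score_mode)
  prof <- cumulative_difference(tpm, design, treatment, control)
  if (!is.null(transcripts))
    prof <- prof[prof$transcript_id %in% transcripts, , drop = FALSE]
  res <- lapply(split(prof, prof$transcript_id), function(df) {
    n <- nrow(df)
    cp <- if (n >= 3) detect_changepoints(df$diff) else
      if (n == 2) 1L else integer()
    se <- segment_enrichment(df, cp)
    d <- se$delta
    data.frame(transcript_id = df$transcript_id[1],
               cp1 = if (length(se$changepoint_positions) >= 1)
                 se$changepoint_positions[1] else NA_integer_,
               cp2 = if (length(se$changepoint_positions) >= 2)
                 se$changepoint_positions[2] else NA_integer_,
               delta_short = if ("short" %in% names(d)) d[["short"]] else NA,
               delta_middle = if ("middle" %in% names(d)) d[["middle"]] else NA,
               delta_long = if ("long" %in% names(d)) d[["long"]] else NA,
               score = tss_switch_score(d, score_mode),
               category = classify_category(d, threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
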