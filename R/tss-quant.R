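## TSS peak filtering, TPM normalization and sliding-window clustering.
##
## A peak table is a data.frame with columns `transcript_id`, `position`
## (nt upstream of the AUG; 0 = AUG-adjacent) and one column per sample.
## A design table maps each sample to a condition and replicate label.

#' Filter TSS peaks by replicate reproducibility
#'
#' A peak is detected in a sample when its count is greater than zero. In
#' `lenient` mode a peak is kept when it is detected in at least n - 1
#' replicates of at least one condition (n = that condition's replicate
#' count); in `strict` mode it must be detected in all replicates of at
#' least one condition. After peak filtering, transcripts whose retained
#' peaks carry fewer than `min_reads` reads summed over all samples are
#' removed entirely.
#'
#' @param counts Peak count table (raw counts).
#' @param design Design table (`sample`, `condition`, `replicate`).
#' @param mode `"lenient"` (n - 1 rule) or `"strict"` (all replicates).
#' @param min_reads Minimum total reads per transcript (default 10).
#' @return The filtered peak count table.
#' @export
filter_reproducible_peaks <- function(counts, design,
                                      mode = c("lenient", "strict"),
                                      min_reads = 10) {
  mode <- match.arg(mode)
  design <- check_design(design, counts)
  sc <- sample_cols(counts, design)
  conds <- unique(design$condition)
  if (max(table(design$condition)) < 2)
    stopf("at least one condition needs >= 2 replicates")

  keep <- rep(FALSE, nrow(counts))
  for (cond in conds) {
    cs <- design$sample[design$condition == cond]
    n <- length(cs)
    det <- rowSums(counts[, cs, drop = FALSE] > 0)
    need <- if (mode == "lenient") max(n - 1L, 1L) else n
    keep <- keep | (det >= need)
  }
  out <- counts[keep, , drop = FALSE]

  tx_tot <- tapply(rowSums(out[, sc, drop = FALSE]), out$transcript_id, sum)
  ok_tx <- names(tx_tot)[tx_tot >= min_reads]
  out <- out[out$transcript_id %in% ok_tx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalize peak counts to tags per million (TPM)
#'
#' Each sample column is divided by its total and scaled by 1e6, so every
#' sample's TPM values sum to one million.
#'
#' @param counts Peak count table.
#' @param design Optional design table; when given, only its samples are
#'   normalized. Otherwise every non-id numeric column is treated as a
#'   sample.
#' @return The table with sample columns replaced by TPM values.
#' @export
normalize_tpm <- function(counts, design = NULL) {
  sc <- if (is.null(design)) setdiff(names(counts), c("transcript_id", "position"))
        else sample_cols(counts, check_design(design, counts))
  for (s in sc) {
    tot <- sum(counts[[s]])
    if (tot <= 0) stopf("sample '%s' has zero total counts", s)
    counts[[s]] <- counts[[s]] / tot * 1e6
  }
  counts
}

#' Remove low-expression TSS peaks within each transcript
#'
#' Within each transcript, a peak is removed when its cross-sample mean TPM
#' falls below `threshold` (default 25%) of the mean over that transcript's
#' peaks of the cross-sample mean TPM. The per-peak summary is the mean
#' over peaks of per-peak cross-sample means, so each replicate carries
#' equal weight; see `?tsswitch` design notes.
#'
#' @param tpm TPM-normalized peak table.
#' @param design Optional design table restricting the sample columns.
#' @param threshold Fraction of the transcript mean below which a peak is
#'   dropped (default 0.25).
#' @return Filtered TPM table.
#' @export
filter_low_expression_peaks <- function(tpm, design = NULL, threshold = 0.25) {
  sc <- if (is.null(design)) setdiff(names(tpm), c("transcript_id", "position"))
        else sample_cols(tpm, check_design(design, tpm))
  peak_mean <- rowMeans(tpm[, sc, drop = FALSE])
  tx_mean <- stats::ave(peak_mean, tpm$transcript_id, FUN = mean)
  out <- tpm[peak_mean >= threshold * tx_mean, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Dynamic window width: 5 nt up to 200 nt, then 2.5% of the longest
# isoform length (ceiling keeps integer nt).
dynamic_window <- function(longest, window = 5L, window_scale = 0.025) {
  if (longest > 200) as.integer(ceiling(window_scale * longest)) else
    as.integer(window)
}

# Chain positions into clusters: a cluster extends while the next peak lies
# within w nt of the last included peak. Returns [lo, hi) intervals.
chain_cluster <- function(positions, w) {
  positions <- sort(unique(positions))
  if (length(positions) == 0)
    return(data.frame(lo = integer(), hi = integer()))
  brk <- c(0L, which(diff(positions) > w), length(positions))
  lo <- positions[brk[-length(brk)] + 1L]
  hi <- positions[brk[-1L]] + 1L
  data.frame(lo = lo, hi = hi)
}

#' Cluster TSS peaks with a dynamic sliding window
#'
#' Clusters are built per transcript (and optionally per condition) by
#' starting at the first TSS peak and extending while the next peak lies
#' within the window of the last included peak. The window is 5 nt, scaled
#' up to 2.5% of the longest isoform length for transcripts whose longest
#' 5'UTR exceeds 200 nt.
#'
#' @param peaks Peak table (typically reproducibility- and
#'   expression-filtered TPM).
#' @param design Optional design table. When given, clusters are formed
#'   separately per condition (using peaks detected in that condition) and
#'   then unified with [unify_clusters()], as positions present in one
#'   condition only would otherwise fragment shared clusters.
#' @param window Base window size (nt).
#' @param window_scale Window fraction of the longest isoform length used
#'   above 200 nt.
#' @return data.frame `transcript_id`, `cluster_id`, `lo`, `hi` with
#'   half-open intervals `[lo, hi)` in nt-upstream coordinates.
#' @export
cluster_tss <- function(peaks, design = NULL, window = 5L,
                        window_scale = 0.025) {
  per_tx <- split(peaks, peaks$transcript_id)
  one_set <- function(df, positions) {
    w <- dynamic_window(max(df$position), window, window_scale)
    chain_cluster(positions, w)
  }
  res <- lapply(names(per_tx), function(tx) {
    df <- per_tx[[tx]]
    if (is.null(design)) {
      cl <- one_set(df, df$position)
    } else {
      design2 <- check_design(design, peaks)
      sets <- lapply(unique(design2$condition), function(cond) {
        cs <- design2$sample[design2$condition == cond]
        one_set(df, df$position[rowSums(df[, cs, drop = FALSE] > 0) > 0])
      })
      cl <- merge_intervals(do.call(rbind, sets))
    }
    if (nrow(cl) == 0) return(NULL)
    data.frame(transcript_id = tx,
               cluster_id = paste0(tx, "_c", seq_len(nrow(cl))),
               lo = cl$lo, hi = cl$hi, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Union of half-open intervals; overlapping or abutting intervals merge.
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0)
    return(data.frame(lo = integer(), hi = integer()))
  iv <- iv[order(iv$lo, iv$hi), , drop = FALSE]
  lo <- iv$lo[1]; hi <- iv$hi[1]
  out_lo <- integer(); out_hi <- integer()
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$lo[i] <= hi) {
      hi <- max(hi, iv$hi[i])
    } else {
      out_lo <- c(out_lo, lo); out_hi <- c(out_hi, hi)
      lo <- iv$lo[i]; hi <- iv$hi[i]
    }
  }
  data.frame(lo = c(out_lo, lo), hi = c(out_hi, hi))
}

#' Unify per-condition cluster sets across conditions
#'
#' Takes cluster tables from the same transcripts (one per condition) and
#' merges overlapping or abutting intervals into a single unified cluster
#' set. Unification is idempotent.
#'
#' @param ... Cluster tables as produced by [cluster_tss()], or a single
#'   list of them.
#' @return A unified cluster table.
#' @export
unify_clusters <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !is.data.frame(sets[[1]]))
    sets <- sets[[1]]
  all <- do.call(rbind, sets)
  res <- lapply(split(all, all$transcript_id), function(df) {
    m <- merge_intervals(df[, c("lo", "hi")])
    data.frame(transcript_id = df$transcript_id[1],
               cluster_id = paste0(df$transcript_id[1], "_c",
                                   seq_len(nrow(m))),
               lo = m$lo, hi = m$hi, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Sum peak expression within clusters
#'
#' Assigns every peak to the cluster whose half-open interval contains its
#' position and sums per-sample values within clusters. Total per-sample
#' expression is conserved when every peak falls inside a cluster.
#'
#' @param clusters Cluster table from [cluster_tss()] / [unify_clusters()].
#' @param peaks Peak table (TPM or raw counts).
#' @param design Optional design restricting sample columns.
#' @return data.frame `transcript_id`, `isoform_id`, `lo`, `hi` plus one
#'   column per sample with summed expression.
#' @export
quantify_clusters <- function(clusters, peaks, design = NULL) {
  sc <- if (is.null(design)) setdiff(names(peaks), c("transcript_id", "position"))
        else sample_cols(peaks, check_design(design, peaks))
  res <- lapply(split(seq_len(nrow(clusters)), clusters$transcript_id),
                function(idx) {
    cl <- clusters[idx, , drop = FALSE]
    pk <- peaks[peaks$transcript_id == cl$transcript_id[1], , drop = FALSE]
    hit <- findInterval(pk$position, sort(cl$lo))
    ord <- order(cl$lo)
    mats <- lapply(seq_len(nrow(cl)), function(i) {
      rows <- pk[hit == i & pk$position < cl$hi[ord][i], sc, drop = FALSE]
      colSums(rows)
    })
    data.frame(transcript_id = cl$transcript_id[1],
               isoform_id = cl$cluster_id[ord],
               lo = cl$lo[ord], hi = cl$hi[ord],
               do.call(rbind, mats),
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Full TSS quantification: filter, normalize, cluster and summarize
#'
#' Runs reproducibility filtering, TPM normalization, low-expression peak
#' filtering, per-condition sliding-window clustering and cross-condition
#' unification, then quantifies cluster (isoform) expression per sample in
#' both TPM and raw-count units.
#'
#' @inheritParams filter_reproducible_peaks
#' @inheritParams cluster_tss
#' @param low_expr Low-expression peak threshold (fraction of transcript
#'   mean, default 0.25).
#' @return A list with `peaks` (filtered raw counts), `peaks_tpm`,
#'   `clusters`, `isoforms_tpm`, `isoforms_counts` and `design`.
#' @export
quantify_tss <- function(counts, design, mode = c("lenient", "strict"),
                         min_reads = 10, low_expr = 0.25, window = 5L,
                         window_scale = 0.025) {
  design <- check_design(design, counts)
  filt <- filter_reproducible_peaks(counts, design, mode, min_reads)
  if (nrow(filt) == 0) stopf("no peaks survive reproducibility filtering")
  tpm <- normalize_tpm(filt, design)
  tpm <- filter_low_expression_peaks(tpm, design, low_expr)
  filt <- filt[paste(filt$transcript_id, filt$position) %in%
                 paste(tpm$transcript_id, tpm$position), , drop = FALSE]
  clusters <- cluster_tss(tpm, design, window, window_scale)
  list(peaks = filt,
       peaks_tpm = tpm,
       clusters = clusters,
       isoforms_tpm = quantify_clusters(clusters, tpm, design),
       isoforms_counts = quantify_clusters(clusters, filt, design),
       design = design)
}

#' Library-complexity saturation curve
#'
#' Subsamples reads (without replacement, in fixed increments) from a peak
#' count table and reports, per sampling depth, the number of unique peaks
#' supported by more than one read and the number of transcripts detected.
#'
#' @param counts Peak count table; all sample columns are pooled.
#' @param increment Reads added per step (default 100,000).
#' @param seed Integer seed for the subsampling order.
#' @return data.frame `reads_sampled`, `unique_peaks`, `transcripts`.
#' @export
saturation_curve <- function(counts, increment = 1e5, seed = 1L) {
  sc <- setdiff(names(counts), c("transcript_id", "position"))
  reads_per_peak <- rowSums(counts[, sc, drop = FALSE])
  total <- sum(reads_per_peak)
  if (total < increment)
    stopf("total reads (%d) below one increment (%d)", total, increment)
  set.seed(as.integer(seed))
  read_ids <- sample(rep.int(seq_len(nrow(counts)), reads_per_peak))
  depths <- unique(c(seq(increment, total, by = increment), total))
  res <- lapply(depths, function(n) {
    tab <- tabulate(read_ids[seq_len(n)], nbins = nrow(counts))
    data.frame(reads_sampled = n,
               unique_peaks = sum(tab > 1),
               transcripts = length(unique(counts$transcript_id[tab > 0])))
  })
  do.call(rbind, res)
}
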