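## Three-arm differential TSS usage test.
##
## Isoforms detected in all samples of both conditions are tested with a
## per-transcript interaction linear model (expression ~ isoform +
## condition + replicate + isoform:condition) on voom-normalized log2
## counts per million, with residual variances moderated by a random
## variance model. Isoforms detected in at least two replicates per
## condition but not all samples are tested with Fisher's exact test on
## condition-summed reads. Isoforms detected in only one condition are
## assessed with the unique-isoform probability. All p-values are pooled
## and adjusted with Benjamini-Hochberg.

#' Assign isoforms to the statistical arms
#'
#' Detection is expression > 0. Per isoform, with detA/detB detections out
#' of nA/nB replicates: `quantitative` when detected in every sample of
#' both conditions; `fisher` when detected in at least two replicates of
#' each condition but not all samples; `unique` when detected in exactly
#' one condition; otherwise `untestable` (for example a single replicate
#' in one condition alongside detections in the other).
#'
#' @param iso Isoform expression table (`transcript_id`, `isoform_id`,
#'   sample columns; counts or TPM).
#' @param design Design table; must have exactly two conditions.
#' @return data.frame `transcript_id`, `isoform_id`, `arm`.
#' @export
route_isoforms <- function(iso, design) {
  design <- check_design(design, iso, n_conditions = 2L)
  conds <- unique(design$condition)
  sa <- design$sample[design$condition == conds[1]]
  sb <- design$sample[design$condition == conds[2]]
  det_a <- rowSums(iso[, sa, drop = FALSE] > 0)
  det_b <- rowSums(iso[, sb, drop = FALSE] > 0)
  arm <- rep("untestable", nrow(iso))
  arm[det_a == length(sa) & det_b == length(sb)] <- "quantitative"
  arm[arm == "untestable" & det_a >= 2 & det_b >= 2] <- "fisher"
  arm[arm == "untestable" &
        ((det_a >= 1 & det_b == 0) | (det_a == 0 & det_b >= 1))] <- "unique"
  data.frame(transcript_id = iso$transcript_id,
             isoform_id = iso$isoform_id, arm = arm,
             stringsAsFactors = FALSE)
}

# Stack a voom E/weight matrix block for one transcript into long vectors
# and fit full/reduced weighted least squares. Returns NULL when the
# interaction is not estimable.
fit_interaction <- function(E, W, design) {
  q <- nrow(E)
  n <- ncol(E)
  dat <- data.frame(
    iso = factor(rep(seq_len(q), each = n)),
    cond = factor(rep(design$condition, q)),
    repl = factor(rep(design$replicate, q)))
  y <- as.vector(t(E))
  w <- as.vector(t(W))
  X1 <- stats::model.matrix(~ iso + cond + repl + iso:cond, dat)
  X0 <- stats::model.matrix(~ iso + cond + repl, dat)
  f1 <- stats::lm.wfit(X1, y, w)
  f0 <- stats::lm.wfit(X0, y, w)
  df1 <- f1$rank - f0$rank
  m <- length(y) - f1$rank
  if (df1 < 1 || m < 1) return(NULL)
  rss1 <- sum(w * f1$residuals^2)
  rss0 <- sum(w * f0$residuals^2)
  # degenerate noiseless data fits exactly; judged on unweighted residuals
  # because precision weights explode at zero estimated variance
  scale <- max(sum((y - mean(y))^2), 1e-300)
  perfect <- sum(f1$residuals^2) <= 1e-12 * scale
  int_zero <- (sum(f0$residuals^2) - sum(f1$residuals^2)) <= 1e-12 * scale
  list(ms_int = (rss0 - rss1) / df1, s2 = rss1 / m, df1 = df1, m = m,
       perfect = perfect, int_zero = int_zero)
}

#' Interaction test for quantitative TSS switching
#'
#' Normalizes cluster counts to precision-weighted log2 counts per million
#' (voom), fits per-transcript weighted least squares of expression on
#' isoform, condition, replicate and the isoform-by-condition interaction,
#' then moderates the interaction F-test with a random variance model
#' fitted across all tested transcripts. A low p-value indicates that
#' isoform usage depends on condition, independent of overall expression
#' and replicate effects.
#'
#' @param iso Isoform raw-count table (`transcript_id`, `isoform_id`,
#'   sample columns).
#' @param design Two-condition design table.
#' @param transcripts Optional transcript subset to test; default all
#'   transcripts with at least two isoforms in `iso`.
#' @param use_weights Propagate voom precision weights into the fits
#'   (default TRUE).
#' @param min_rvm Below this number of tested transcripts the hyperparameter
#'   fit is unstable and the unmoderated F-test is used (default 50).
#' @param lib_size Library sizes for the log-CPM transform; defaults to the
#'   column sums of `iso` (pass totals from the full peak table when `iso`
#'   is a subset).
#' @return data.frame `transcript_id`, `n_isoforms`, `f_stat`, `df1`,
#'   `df2`, `p_value`, with the RVM fit in attribute `"rvm"`.
#' @export
quant_interaction_test <- function(iso, design, transcripts = NULL,
                                   use_weights = TRUE, min_rvm = 50,
                                   lib_size = NULL) {
  design <- check_design(design, iso, n_conditions = 2L)
  sc <- design$sample
  if (is.null(transcripts)) {
    tab <- table(iso$transcript_id)
    transcripts <- names(tab)[tab >= 2]
  }
  rows <- iso$transcript_id %in% transcripts
  if (!any(rows)) stopf("no transcripts with >= 2 isoforms to test")
  counts <- as.matrix(iso[rows, sc, drop = FALSE])
  tx <- iso$transcript_id[rows]
  if (is.null(lib_size)) lib_size <- colSums(as.matrix(iso[, sc, drop = FALSE]))

  mm <- stats::model.matrix(~ condition, design)
  v <- limma::voom(counts, design = mm, lib.size = lib_size)
  E <- v$E
  W <- if (use_weights) v$weights else matrix(1, nrow(E), ncol(E))

  idx <- split(seq_along(tx), tx)
  fits <- lapply(idx, function(i)
    fit_interaction(E[i, , drop = FALSE], W[i, , drop = FALSE], design))
  ok <- !vapply(fits, is.null, logical(1))
  fits <- fits[ok]
  if (length(fits) == 0) stopf("no estimable interaction models")

  s2 <- vapply(fits, `[[`, numeric(1), "s2")
  m <- vapply(fits, `[[`, numeric(1), "m")
  ms <- vapply(fits, `[[`, numeric(1), "ms_int")
  df1 <- vapply(fits, `[[`, numeric(1), "df1")

  if (length(fits) >= min_rvm) {
    rvm <- rvm_fit(s2, m)
    s2_use <- rvm_shrink(s2, m, rvm)
    df2 <- m + 2 * rvm$a
  } else {
    rvm <- NULL
    s2_use <- s2
    df2 <- m
  }
  fstat <- pmax(ms, 0) / s2_use
  # numerically perfect fits: no residual variance means F = 0 when the
  # interaction adds nothing, Inf when it alone absorbs the data
  perfect <- vapply(fits, `[[`, logical(1), "perfect")
  int_zero <- vapply(fits, `[[`, logical(1), "int_zero")
  fstat[perfect] <- ifelse(int_zero[perfect], 0, Inf)
  res <- data.frame(transcript_id = names(fits),
                    n_isoforms = df1 + 1L,
                    f_stat = fstat, df1 = df1, df2 = df2,
                    p_value = stats::pf(fstat, df1, df2, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "rvm") <- rvm
  res
}

#' Fisher's exact test arm for partially detected isoforms
#'
#' For each requested isoform, builds the 2x2 table of condition-summed
#' reads for the isoform versus all other isoforms of its transcript and
#' applies a two-sided Fisher's exact test.
#'
#' @param iso Isoform raw-count table.
#' @param design Two-condition design table.
#' @param isoform_ids Isoforms to test (default all).
#' @return data.frame `transcript_id`, `isoform_id`, `p_value` plus the
#'   2x2 table entries.
#' @export
fisher_arm <- function(iso, design, isoform_ids = NULL) {
  design <- check_design(design, iso, n_conditions = 2L)
  conds <- unique(design$condition)
  sa <- design$sample[design$condition == conds[1]]
  sb <- design$sample[design$condition == conds[2]]
  ra <- rowSums(iso[, sa, drop = FALSE])
  rb <- rowSums(iso[, sb, drop = FALSE])
  tot_a <- stats::ave(ra, iso$transcript_id, FUN = sum)
  tot_b <- stats::ave(rb, iso$transcript_id, FUN = sum)
  sel <- if (is.null(isoform_ids)) seq_len(nrow(iso)) else
    which(iso$isoform_id %in% isoform_ids)
  p <- vapply(sel, function(i) {
    tab <- round(matrix(c(ra[i], tot_a[i] - ra[i],
                          rb[i], tot_b[i] - rb[i]), nrow = 2))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  data.frame(transcript_id = iso$transcript_id[sel],
             isoform_id = iso$isoform_id[sel],
             reads_a = ra[sel], other_a = tot_a[sel] - ra[sel],
             reads_b = rb[sel], other_b = tot_b[sel] - rb[sel],
             p_value = pmin(p, 1), stringsAsFactors = FALSE)
}

#' Probability of observing only shared isoforms in the other condition
#'
#' For an isoform expressed uniquely in condition i, computes
#' `(r_si / (r_ui + r_si)) ^ r_sj`: under condition-i isoform proportions,
#' the probability that all `r_sj` reads observed in condition j come from
#' the shared isoforms, i.e. that the unique isoform is missed by chance.
#' Reads are summed across replicates.
#'
#' @param r_si Shared-isoform reads in the condition expressing the unique
#'   isoform.
#' @param r_ui Unique-isoform reads in that condition (must be >= 1).
#' @param r_sj Shared-isoform reads in the other condition.
#' @return Probabilities in `[0, 1]`, vectorized over the inputs.
#' @export
unique_isoform_probability <- function(r_si, r_ui, r_sj) {
  n <- max(length(r_si), length(r_ui), length(r_sj))
  r_si <- rep_len(r_si, n); r_ui <- rep_len(r_ui, n)
  r_sj <- rep_len(r_sj, n)
  if (any(r_si < 0) || any(r_sj < 0)) stopf("read counts must be >= 0")
  if (any(r_ui < 1)) stopf("r_ui must be >= 1 (a unique isoform exists)")
  if (any(r_ui + r_si == 0)) stopf("r_ui + r_si must be positive")
  p <- (r_si / (r_ui + r_si))^r_sj
  p[r_sj == 0] <- 1  # empty product, also covers 0^0
  p
}

#' Benjamini-Hochberg adjustment of pooled arm p-values
#'
#' @param p Numeric p-values in `[0, 1]` pooled from all tested units.
#' @return Adjusted values (step-up with enforced monotonicity).
#' @export
adjust_fdr <- function(p) bh_adjust(p)

#' Three-arm test for differential TSS usage
#'
#' Routes every isoform to its arm ([route_isoforms()]), runs the
#' random-variance-model moderated interaction test per transcript on
#' fully detected isoforms, Fisher's exact test per partially detected
#' isoform and the unique-isoform probability per condition-specific
#' isoform, pools all p-values under Benjamini-Hochberg and flags
#' significance at `fdr < fdr_threshold`. Quantitative isoforms belonging
#' to transcripts with fewer than two fully detected isoforms cannot enter
#' the interaction model and are tested in the Fisher arm instead (they
#' meet its detection requirement by construction).
#'
#' @param iso Isoform raw-count table (`transcript_id`, `isoform_id`,
#'   sample columns), e.g. `quantify_tss(...)$isoforms_counts`.
#' @param design Two-condition design table.
#' @param fdr_threshold Significance threshold on the adjusted p (default
#'   0.15).
#' @inheritParams quant_interaction_test
#' @return An object of class `tss_switch_test`: a list with `results`
#'   (one row per tested unit: `transcript_id`, `isoform_id` (NA for
#'   transcript-level quantitative rows), `arm`, `p_value`, `fdr`,
#'   `significant`), `arms` (the per-isoform routing), `rvm`,
#'   `fdr_threshold` and `design`.
#' @export
test_tss_switching <- function(iso, design, fdr_threshold = 0.15,
                               use_weights = TRUE, min_rvm = 50) {
  design <- check_design(design, iso, n_conditions = 2L)
  arms <- route_isoforms(iso, design)

  quant_tab <- table(arms$transcript_id[arms$arm == "quantitative"])
  quant_tx <- names(quant_tab)[quant_tab >= 2]
  demote <- arms$arm == "quantitative" & !(arms$transcript_id %in% quant_tx)
  arms$arm[demote] <- "fisher"

  blocks <- list()
  if (length(quant_tx) > 0) {
    qi <- iso[arms$arm == "quantitative", , drop = FALSE]
    qt <- quant_interaction_test(qi, design, transcripts = quant_tx,
                                 use_weights = use_weights,
                                 min_rvm = min_rvm,
                                 lib_size = colSums(as.matrix(
                                   iso[, design$sample, drop = FALSE])))
    blocks$quant <- data.frame(transcript_id = qt$transcript_id,
                               isoform_id = NA_character_,
                               arm = "quantitative", p_value = qt$p_value,
                               stringsAsFactors = FALSE)
    rvm <- attr(qt, "rvm")
  } else rvm <- NULL

  fish_ids <- arms$isoform_id[arms$arm == "fisher"]
  if (length(fish_ids) > 0) {
    ft <- fisher_arm(iso, design, fish_ids)
    blocks$fisher <- data.frame(transcript_id = ft$transcript_id,
                                isoform_id = ft$isoform_id, arm = "fisher",
                                p_value = ft$p_value,
                                stringsAsFactors = FALSE)
  }

  uniq <- arms$arm == "unique"
  if (any(uniq)) {
    conds <- unique(design$condition)
    sa <- design$sample[design$condition == conds[1]]
    sb <- design$sample[design$condition == conds[2]]
    ra <- rowSums(iso[, sa, drop = FALSE])
    rb <- rowSums(iso[, sb, drop = FALSE])
    tot_a <- stats::ave(ra, iso$transcript_id, FUN = sum)
    tot_b <- stats::ave(rb, iso$transcript_id, FUN = sum)
    w <- which(uniq)
    pu <- vapply(w, function(i) {
      in_a <- ra[i] > 0
      r_ui <- round(if (in_a) ra[i] else rb[i])
      r_si <- round(if (in_a) tot_a[i] - ra[i] else tot_b[i] - rb[i])
      r_sj <- round(if (in_a) tot_b[i] else tot_a[i])
      unique_isoform_probability(r_si, max(r_ui, 1), r_sj)
    }, numeric(1))
    blocks$unique <- data.frame(transcript_id = iso$transcript_id[w],
                                isoform_id = iso$isoform_id[w],
                                arm = "unique", p_value = pu,
                                stringsAsFactors = FALSE)
  }

  results <- do.call(rbind, blocks)
  if (is.null(results) || nrow(results) == 0)
    stopf("no testable isoforms or transcripts")
  results <- results[order(results$transcript_id, results$isoform_id,
                           na.last = FALSE), , drop = FALSE]
  results$fdr <- adjust_fdr(results$p_value)
  results$significant <- results$fdr < fdr_threshold
  rownames(results) <- NULL

  structure(list(results = results, arms = arms, rvm = rvm,
                 fdr_threshold = fdr_threshold, design = design),
            class = "tss_switch_test")
}

#' Transcripts with significant TSS switching
#'
#' @param x A `tss_switch_test` object.
#' @return Character vector of transcript ids with at least one
#'   significant tested unit.
#' @export
significant_transcripts <- function(x) {
  stopifnot(inherits(x, "tss_switch_test"))
  sort(unique(x$results$transcript_id[x$results$significant]))
}

#' @export
print.tss_switch_test <- function(x, ...) {
  n_tx <- length(unique(x$results$transcript_id))
  n_sig <- length(significant_transcripts(x))
  cat("Differential TSS usage test (three-arm, BH-pooled)\n")
  cat(sprintf("  %d tested units over %d transcripts\n",
              nrow(x$results), n_tx))
  print(table(arm = x$results$arm))
  cat(sprintf("  %d transcripts significant at FDR < %.2f\n",
              n_sig, x$fdr_threshold))
  invisible(x)
}

#' @export
summary.tss_switch_test <- function(object, ...) {
  out <- list(arm_counts = table(object$results$arm),
              routed = table(object$arms$arm),
              n_significant = length(significant_transcripts(object)),
              fdr_threshold = object$fdr_threshold,
              rvm = object$rvm)
  class(out) <- "summary.tss_switch_test"
  out
}

#' @export
print.summary.tss_switch_test <- function(x, ...) {
  cat("Tested units by arm:\n"); print(x$arm_counts)
  cat("Isoform routing (before demotion of lone quantitative isoforms):\n")
  print(x$routed)
  cat(sprintf("Significant transcripts at FDR < %.2f: %d\n",
              x$fdr_threshold, x$n_significant))
  if (!is.null(x$rvm))
    cat(sprintf("RVM hyperparameters: a = %.3f, b = %.3f (prior var %.4f)\n",
                x$rvm$a, x$rvm$b, x$rvm$prior_var))
  invisible(x)
}
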