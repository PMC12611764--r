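## Shared I/O and the end-to-end pipeline driver. Interchange dialect is
## TSV (tab-separated, UTF-8, '.' decimal) with a header and stable column
## order.

#' Read a TSS peak count table from TSV
#'
#' Expects columns `transcript_id`, `position` and one column per sample.
#'
#' @param path TSV file path.
#' @return data.frame peak table.
#' @export
read_tss_counts <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  req <- c("transcript_id", "position")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stopf("count table %s is missing column(s): %s", path,
          paste(miss, collapse = ", "))
  tab
}

#' Read a design table from TSV
#'
#' Expects columns `sample`, `condition`, `replicate`.
#'
#' @param path TSV file path.
#' @return Validated design data.frame.
#' @export
read_design <- function(path) {
  check_design(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a table as TSV
#'
#' @param x data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the TSS-switching pipeline end to end
#'
#' Quantifies TSS clusters ([quantify_tss()]), tests differential TSS
#' usage ([test_tss_switching()]) and scores significant switching
#' transcripts by change-point segmentation ([score_tss_switching()]).
#' When `out_dir` is given, result TSVs and a JSON manifest (thresholds,
#' seed-independent row counts) are written; re-running with the same
#' inputs reproduces identical files.
#'
#' @param counts Peak count table (see [read_tss_counts()]).
#' @param design Design table.
#' @param treatment,control Condition labels.
#' @param mode Reproducibility filter mode (default `"lenient"`).
#' @param fdr_threshold Switching significance threshold (default 0.15).
#' @param score_all Score all transcripts rather than significant ones
#'   only (useful when the score is a downstream covariate; default
#'   FALSE).
#' @param out_dir Optional output directory.
#' @param ... Further arguments to [quantify_tss()].
#' @return A list with `quant`, `test` (a `tss_switch_test`) and `scores`.
#' @export
run_pipeline <- function(counts, design, treatment, control,
                         mode = "lenient", fdr_threshold = 0.15,
                         score_all = FALSE, out_dir = NULL, ...) {
  design <- check_design(design, counts, n_conditions = 2L)
  if (!all(c(treatment, control) %in% design$condition))
    stopf("treatment/control labels not present in design$condition")
  quant <- quantify_tss(counts, design, mode = mode, ...)
  test <- test_tss_switching(quant$isoforms_counts, design,
                             fdr_threshold = fdr_threshold)
  tx <- if (score_all) NULL else significant_transcripts(test)
  scores <- if (score_all || length(tx) > 0)
    score_tss_switching(quant$peaks_tpm, design, treatment, control,
                        transcripts = tx)
  else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(quant$clusters, file.path(out_dir, "clusters.tsv"))
    write_tsv(quant$isoforms_tpm, file.path(out_dir, "isoforms_tpm.tsv"))
    write_tsv(test$results, file.path(out_dir, "switch_test.tsv"))
    if (!is.null(scores))
      write_tsv(scores, file.path(out_dir, "switch_scores.tsv"))
    manifest <- list(
      package = "tsswitch",
      version = as.character(utils::packageVersion("tsswitch")),
      treatment = treatment, control = control, mode = mode,
      fdr_threshold = fdr_threshold,
      rows = list(peaks = nrow(quant$peaks),
                  clusters = nrow(quant$clusters),
                  tested = nrow(test$results),
                  significant = length(significant_transcripts(test)),
                  scored = if (is.null(scores)) 0L else nrow(scores)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(quant = quant, test = test, scores = scores)
}
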