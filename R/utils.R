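## Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Stop with a message assembled sprintf-style; keeps call noise out of errors.
stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Validate a design table: one row per sample, columns sample/condition/replicate.
check_design <- function(design, counts = NULL, n_conditions = NULL) {
  req <- c("sample", "condition", "replicate")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols) > 0L)
    stopf("design is missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(design$sample))
    stopf("design has duplicated sample names")
  if (!is.null(n_conditions)) {
    k <- length(unique(design$condition))
    if (k != n_conditions)
      stopf("design must have exactly %d conditions, found %d", n_conditions, k)
  }
  if (!is.null(counts)) {
    absent <- setdiff(design$sample, names(counts))
    if (length(absent) > 0L)
      stopf("design sample(s) not found in count table: %s",
            paste(absent, collapse = ", "))
  }
  design$sample <- as.character(design$sample)
  design$condition <- as.character(design$condition)
  design$replicate <- as.character(design$replicate)
  design
}

# Columns of a peak/cluster table that hold per-sample values.
sample_cols <- function(tab, design) {
  intersect(design$sample, names(tab))
}

# Benjamini-Hochberg with stable (p, id) tie-break, via stats::p.adjust.
# p.adjust is already deterministic for ties; the stable ordering matters only
# for downstream row ordering, which callers handle themselves.
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
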