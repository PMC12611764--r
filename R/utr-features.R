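## 5'UTR feature operations: expression-weighted summaries, dominant
## isoform, uORF counting, TOPscore and IUPAC motif occupancy changes.

normalize_rna <- function(seq) {
  s <- chartr("acgut", "ACGUT", seq)
  s <- gsub("T", "U", s)
  bad <- grepl("[^ACGU]", s)
  if (any(bad))
    stopf("sequence contains non-ACGT/U symbols: %s",
          paste(unique(unlist(strsplit(gsub("[ACGU]", "", s[bad]), ""))),
                collapse = ""))
  s
}

#' Expression-weighted 5'UTR summaries
#'
#' Weighted mean of per-isoform values (typically length or GC fraction)
#' with weights equal to each isoform's relative expression in a
#' condition.
#'
#' @param values Per-isoform values.
#' @param expression Per-isoform expression in the condition (any scale;
#'   weights are normalized internally).
#' @return The weighted mean; `NA` with a warning when total expression is
#'   zero.
#' @export
weighted_utr_stat <- function(values, expression) {
  stopifnot(length(values) == length(expression))
  tot <- sum(expression)
  if (tot <= 0) {
    warnf("zero total expression; weighted statistic undefined")
    return(NA_real_)
  }
  sum(values * expression) / tot
}

#' GC fraction of a sequence
#'
#' @param seq Character vector of RNA/DNA sequences.
#' @return GC fraction in `[0, 1]` per sequence.
#' @export
gc_fraction <- function(seq) {
  s <- normalize_rna(seq)
  vapply(s, function(x) {
    n <- nchar(x)
    if (n == 0) return(NA_real_)
    (n - nchar(gsub("[GC]", "", x))) / n
  }, numeric(1), USE.NAMES = FALSE)
}

#' Dominant 5'UTR isoform
#'
#' The isoform with the highest expression; ties are broken by taking the
#' longest isoform.
#'
#' @param expression Per-isoform expression.
#' @param lengths Per-isoform 5'UTR lengths (nt).
#' @return Index of the dominant isoform.
#' @export
dominant_isoform <- function(expression, lengths) {
  stopifnot(length(expression) == length(lengths), length(expression) >= 1)
  top <- which(expression == max(expression))
  top[which.max(lengths[top])]
}

#' Count upstream open reading frames in a 5'UTR
#'
#' Counts AUG triplets with an in-frame stop codon (UAA/UAG/UGA) contained
#' entirely within the 5'UTR (fully upstream uORFs). With
#' `include_overlapping = TRUE`, AUGs without an in-frame stop before the
#' 3' end (ORFs running into the CDS) are counted too.
#'
#' @param seq A single 5'UTR sequence (RNA or DNA alphabet, 5' to 3').
#' @param include_overlapping Count CDS-overlapping uORFs as well
#'   (default FALSE).
#' @return Integer uORF count.
#' @export
count_uorfs <- function(seq, include_overlapping = FALSE) {
  s <- normalize_rna(seq)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  if (n < 3) return(0L)
  codon_at <- function(i) paste0(chars[i], chars[i + 1], chars[i + 2])
  stops <- c("UAA", "UAG", "UGA")
  count <- 0L
  for (i in seq_len(n - 2)) {
    if (codon_at(i) != "AUG") next
    has_stop <- FALSE
    j <- i + 3
    while (j + 2 <= n) {
      if (codon_at(j) %in% stops) { has_stop <- TRUE; break }
      j <- j + 3
    }
    if (has_stop || include_overlapping) count <- count + 1L
  }
  count
}

# TOP motif at the transcription start: +1 C (or U in permissive mode)
# followed by >= 4 pyrimidines.
is_top_start <- function(seq, min_pyrimidines = 4L, permissive = FALSE) {
  s <- normalize_rna(seq)
  first_ok <- substr(s, 1, 1) == "C" |
    (permissive & substr(s, 1, 1) == "U")
  tail_ok <- vapply(s, function(x) {
    run <- regmatches(x, regexpr("^[CU]+", x))
    if (length(run) == 0) 0L else nchar(run) - 1L
  }, integer(1), USE.NAMES = FALSE) >= min_pyrimidines
  first_ok & tail_ok
}

#' TOPscore: expression-weighted prevalence of TOP-initiating TSSs
#'
#' Sums, over a gene's TSS positions, the relative expression of positions
#' whose transcript starts with a 5'-terminal oligopyrimidine motif (C at
#' +1 followed by at least four pyrimidines; a permissive mode also
#' accepts U at +1). A gene whose whole expression starts at TOP motifs
#' scores 1. Positions with a missing sequence are skipped with a warning.
#'
#' @param expression Relative (or raw) expression per TSS position.
#' @param sequences 5'-end sequence context per TSS (the transcript
#'   starting at that position, 5' to 3'); `NA` to skip.
#' @param min_pyrimidines Pyrimidines required after +1 (default 4).
#' @param permissive Accept U at +1 (default FALSE).
#' @return TOPscore in `[0, 1]`.
#' @export
top_score <- function(expression, sequences, min_pyrimidines = 4L,
                      permissive = FALSE) {
  stopifnot(length(expression) == length(sequences))
  miss <- is.na(sequences)
  if (any(miss)) {
    warnf("%d TSS position(s) without sequence skipped", sum(miss))
    expression <- expression[!miss]; sequences <- sequences[!miss]
  }
  tot <- sum(expression)
  if (tot <= 0) return(0)
  sum(expression[is_top_start(sequences, min_pyrimidines, permissive)]) / tot
}

# IUPAC-aware substring presence per sequence, via Biostrings.
motif_present <- function(sequences, motif) {
  dna <- gsub("U", "T", chartr("acgut", "ACGUT", sequences))
  motif_dna <- gsub("U", "T", toupper(motif))
  if (!all(strsplit(motif_dna, "")[[1]] %in%
             names(Biostrings::IUPAC_CODE_MAP)))
    stopf("motif '%s' contains invalid IUPAC symbols", motif)
  subj <- Biostrings::DNAStringSet(dna)
  Biostrings::vcountPattern(motif_dna, subj, fixed = FALSE) > 0
}

#' Motif gain or loss through TSS switching
#'
#' Compares the expression fraction carried by motif-containing 5'UTR
#' isoforms between conditions: `gained` when the fraction increases by
#' more than `threshold` (default 10 percentage points of expression),
#' `lost` when it decreases by more, else `unchanged`. Motifs are IUPAC
#' strings matched as substrings. With `weighting = "count"` the fraction
#' of expressed isoforms (unweighted) is compared instead.
#'
#' @param sequences Per-isoform 5'UTR sequences.
#' @param expr_ctrl,expr_treat Per-isoform expression in control and
#'   treatment.
#' @param motif IUPAC motif string (e.g. `"SGCSGCS"`).
#' @param threshold Change in motif-bearing fraction required (default
#'   0.10).
#' @param weighting `"expression"` (default) or `"count"`.
#' @return A list with `status` (`gained`/`lost`/`unchanged`), `f_ctrl`
#'   and `f_treat`.
#' @export
motif_occupancy_change <- function(sequences, expr_ctrl, expr_treat, motif,
                                   threshold = 0.10,
                                   weighting = c("expression", "count")) {
  weighting <- match.arg(weighting)
  has <- motif_present(sequences, motif)
  frac <- function(expr) {
    if (weighting == "count") {
      on <- expr > 0
      if (!any(on)) return(NA_real_)
      mean(has[on])
    } else {
      tot <- sum(expr)
      if (tot <= 0) return(NA_real_)
      sum(expr[has]) / tot
    }
  }
  f_c <- frac(expr_ctrl); f_t <- frac(expr_treat)
  d <- f_t - f_c
  status <- if (is.na(d)) NA_character_
    else if (d > threshold) "gained"
    else if (d < -threshold) "lost"
    else "unchanged"
  list(status = status, f_ctrl = f_c, f_treat = f_t)
}

#' Read 5'UTR isoform sequences from FASTA
#'
#' Record ids are expected as `transcript_id|isoform_id`; a missing
#' separator leaves `isoform_id` equal to the transcript id.
#'
#' @param path FASTA file path.
#' @return data.frame `transcript_id`, `isoform_id`, `sequence`, `length`.
#' @export
read_utr_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  parts <- strsplit(ids, "|", fixed = TRUE)
  data.frame(
    transcript_id = vapply(parts, `[`, character(1), 1),
    isoform_id = vapply(parts, function(p) p[length(p)], character(1)),
    sequence = as.character(ss),
    length = Biostrings::width(ss),
    stringsAsFactors = FALSE, row.names = NULL)
}
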