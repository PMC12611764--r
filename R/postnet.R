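## Stepwise variance-partition modelling of translational regulation
## (postNet-style): univariate screen, forward selection with covariance
## edges, semi-partial variance decomposition, and the quartile-bin ECDF
## shift analysis.

# A feature enters modelling only when it is non-constant on at least
# `covar_filt` genes: the count of values differing from the modal value
# must reach the filter (for a 0/1 signature this is the minority count).
passes_covar_filter <- function(x, covar_filt = 8L) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(FALSE)
  tab <- table(x)
  length(x) - max(tab) >= covar_filt
}

r_squared <- function(y, X) {
  if (NCOL(X) == 0) return(0)
  fit <- stats::lm.fit(cbind(1, as.matrix(X)), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Univariate screen of features against a regulation vector
#'
#' Ordinary least squares of the regulation vector on each feature
#' separately, reporting R-squared, the two-sided p-value and the slope
#' sign. Constant features (per the covariate filter) are skipped and
#' listed in attribute `"skipped"`.
#'
#' @param y Numeric regulation vector (e.g. log2 fold change of
#'   translation efficiency or offsetting), one value per gene.
#' @param X data.frame or matrix of features (genes x features).
#' @param covar_filt Minimum number of genes on which a feature must be
#'   non-constant (default 8).
#' @return data.frame `feature`, `r2`, `p_value`, `sign`, ordered by
#'   decreasing R-squared (ties broken lexicographically by feature name).
#' @export
univariate_screen <- function(y, X, covar_filt = 8L) {
  X <- as.data.frame(X)
  stopifnot(length(y) == nrow(X))
  ok <- vapply(X, passes_covar_filter, logical(1), covar_filt = covar_filt)
  skipped <- names(X)[!ok]
  res <- lapply(names(X)[ok], function(f) {
    fit <- stats::lm(y ~ x, data = data.frame(y = y, x = X[[f]]))
    sm <- summary(fit)
    data.frame(feature = f, r2 = sm$r.squared,
               p_value = sm$coefficients["x", "Pr(>|t|)"],
               sign = sign(sm$coefficients["x", "Estimate"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(feature = character(), r2 = numeric(),
                                      p_value = numeric(), sign = numeric())
  out <- out[order(-out$r2, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Forward stepwise integration with covariance edges
#'
#' Seeds the model with the top univariate feature (if significant at
#' `alpha`) and iteratively adds the candidate with the best partial
#' F-test p-value while it stays below `alpha`. Whenever a candidate is
#' evaluated against the current model, an edge is recorded between the
#' candidate and any included variable that absorbs more than
#' `edge_threshold` of the candidate's marginal R-squared (pairwise shared
#' variance `R2(c) + R2(u) - R2(c,u)`), revealing covariance between
#' variables. Continuous features are standardized before selection;
#' binary 0/1 columns are left as is. Ties in candidate order are broken
#' lexicographically, so selection is invariant to column order.
#'
#' @inheritParams univariate_screen
#' @param alpha Partial F-test inclusion threshold (default 0.05).
#' @param edge_threshold Shared variance above which an edge is recorded
#'   (default 0.10).
#' @param screen Optional precomputed [univariate_screen()] result.
#' @return A list with `selected` (features in selection order), `edges`
#'   (data.frame `from`, `to`, `shared`), `screen` and the standardized
#'   feature matrix `X`.
#' @export
stepwise_integration <- function(y, X, alpha = 0.05, edge_threshold = 0.10,
                                 covar_filt = 8L, screen = NULL) {
  X <- as.data.frame(X)
  if (is.null(screen)) screen <- univariate_screen(y, X, covar_filt)
  Xs <- X[, screen$feature, drop = FALSE]
  is_binary <- vapply(Xs, function(x) all(x %in% c(0, 1)), logical(1))
  Xs[!is_binary] <- lapply(Xs[!is_binary], function(x)
    (x - mean(x)) / stats::sd(x))

  edges <- list()
  selected <- character()
  if (nrow(screen) == 0 || min(screen$p_value) >= alpha) {
    warnf("no significant univariate feature; empty model")
    return(list(selected = selected,
                edges = data.frame(from = character(), to = character(),
                                   shared = numeric()),
                screen = screen, X = Xs))
  }
  marg <- stats::setNames(screen$r2, screen$feature)
  selected <- screen$feature[1]
  rss <- function(set) {
    fit <- stats::lm.fit(cbind(1, as.matrix(Xs[, set, drop = FALSE])), y)
    sum(fit$residuals^2)
  }
  n <- length(y)
  repeat {
    candidates <- sort(setdiff(screen$feature, selected))
    if (length(candidates) == 0) break
    rss_cur <- rss(selected)
    p_cur <- length(selected) + 1L
    stats_c <- vapply(candidates, function(f) {
      rss_new <- rss(c(selected, f))
      df2 <- n - p_cur - 1L
      fstat <- (rss_cur - rss_new) / (rss_new / df2)
      stats::pf(fstat, 1, df2, lower.tail = FALSE)
    }, numeric(1))
    # covariance edges: shared variance between each candidate and each
    # included variable, recorded whenever it exceeds the threshold
    for (f in candidates) {
      for (u in selected) {
        shared <- marg[f] + marg[u] -
          (1 - rss(c(f, u)) / sum((y - mean(y))^2))
        if (is.finite(shared) && shared > edge_threshold)
          edges[[paste(u, f, sep = "~")]] <-
            data.frame(from = u, to = f, shared = shared,
                       stringsAsFactors = FALSE)
      }
    }
    best <- which.min(stats_c)
    if (!is.finite(stats_c[best]) || stats_c[best] >= alpha) break
    selected <- c(selected, candidates[best])
  }
  edges <- if (length(edges) > 0) {
    e <- do.call(rbind, unname(edges))
    e[!duplicated(paste(e$from, e$to)), , drop = FALSE]
  } else data.frame(from = character(), to = character(), shared = numeric())
  rownames(edges) <- NULL
  list(selected = selected, edges = edges, screen = screen, X = Xs)
}

#' Unique (semi-partial) variance decomposition of the selected model
#'
#' For each selected variable, the unique percentage of variance is
#' `100 * (R2_full - R2_without)`: the explained variance lost when the
#' variable is removed, i.e. its contribution adjusted for all others.
#'
#' @param y Regulation vector.
#' @param X Feature matrix (standardized, as returned by
#'   [stepwise_integration()]).
#' @param selected Selected feature names.
#' @param edges Optional edge table to carry through.
#' @param signs Optional named slope signs from the univariate screen.
#' @return An object of class `postnet_fit` with `selected`, `unique_pct`
#'   (named), `total_pct`, `unexplained_pct`, `edges`, `signs`.
#' @export
partial_variance <- function(y, X, selected, edges = NULL, signs = NULL) {
  X <- as.data.frame(X)
  r2_full <- r_squared(y, X[, selected, drop = FALSE])
  unique_pct <- vapply(selected, function(f)
    100 * (r2_full - r_squared(y, X[, setdiff(selected, f), drop = FALSE])),
    numeric(1))
  structure(list(selected = selected,
                 unique_pct = unique_pct,
                 total_pct = 100 * r2_full,
                 unexplained_pct = 100 * (1 - r2_full),
                 edges = edges, signs = signs),
            class = "postnet_fit")
}

#' postNet-style feature integration
#'
#' Runs the three steps of the variance-partition network model: the
#' univariate screen, forward stepwise integration with covariance edges,
#' and the semi-partial variance decomposition of the final model.
#'
#' @inheritParams stepwise_integration
#' @return A `postnet_fit` (see [partial_variance()]) with the screen and
#'   selection attached.
#' @export
postnet <- function(y, X, alpha = 0.05, edge_threshold = 0.10,
                    covar_filt = 8L) {
  step <- stepwise_integration(y, X, alpha, edge_threshold, covar_filt)
  signs <- stats::setNames(step$screen$sign, step$screen$feature)
  fit <- partial_variance(y, step$X, step$selected, step$edges,
                          signs[step$selected])
  fit$screen <- step$screen
  fit
}

#' @export
print.postnet_fit <- function(x, ...) {
  cat("postNet variance-partition model\n")
  if (length(x$selected) == 0) {
    cat("  no variables selected; unexplained 100%\n")
    return(invisible(x))
  }
  cat(sprintf("  explained %.1f%%, unexplained %.1f%%\n",
              x$total_pct, x$unexplained_pct))
  df <- data.frame(feature = x$selected,
                   unique_pct = round(x$unique_pct[x$selected], 2))
  if (!is.null(x$signs))
    df$sign <- ifelse(x$signs[x$selected] >= 0, "+", "-")
  print(df, row.names = FALSE)
  if (!is.null(x$edges) && nrow(x$edges) > 0)
    cat(sprintf("  %d covariance edge(s) above threshold\n", nrow(x$edges)))
  invisible(x)
}

#' Quartile-bin ECDF shift analysis of scores versus regulation
#'
#' Takes the `n_top` most up- and downregulated genes by fold change,
#' splits each direction into `n_bins` equal bins by fold-change
#' quartiles, and compares each bin's score distribution to the background
#' (all genes not in any bin) with a two-sided Wilcoxon rank-sum test,
#' reporting the score shift at the 25th/50th/75th percentiles.
#'
#' @param scores Per-gene scores (e.g. TSS-switch scores).
#' @param fold_change Per-gene regulation fold changes (log2).
#' @param n_top Genes taken per direction (default 400; shrunk with a
#'   warning when fewer are available).
#' @param n_bins Bins per direction (default 4).
#' @return data.frame with one row per bin: `direction`, `bin`, `n`,
#'   `p_value` and `shift_q25`/`shift_q50`/`shift_q75` (bin minus
#'   background score quantiles).
#' @export
ecdf_bin_shift <- function(scores, fold_change, n_top = 400L, n_bins = 4L) {
  stopifnot(length(scores) == length(fold_change))
  n <- length(scores)
  if (n < 3 * n_top) {
    # shrink so that a background set remains alongside the two tails
    n_top <- floor(n / 3)
    warnf("fewer genes than 3 * n_top; using %d per direction", n_top)
  }
  ord <- order(fold_change)
  down <- ord[seq_len(n_top)]
  up <- rev(ord)[seq_len(n_top)]
  background <- setdiff(seq_len(n), c(up, down))
  one_dir <- function(idx, direction) {
    fc <- fold_change[idx]
    qs <- stats::quantile(fc, probs = seq(0, 1, length.out = n_bins + 1))
    bin <- cut(fc, breaks = unique(qs), include.lowest = TRUE,
               labels = FALSE)
    do.call(rbind, lapply(seq_len(max(bin)), function(b) {
      sc <- scores[idx[bin == b]]
      bg <- scores[background]
      p <- stats::wilcox.test(sc, bg, exact = FALSE)$p.value
      sh <- stats::quantile(sc, c(0.25, 0.5, 0.75)) -
        stats::quantile(bg, c(0.25, 0.5, 0.75))
      data.frame(direction = direction, bin = b, n = length(sc),
                 p_value = p, shift_q25 = sh[1], shift_q50 = sh[2],
                 shift_q75 = sh[3], stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(one_dir(down, "down"), one_dir(up, "up"))
  rownames(out) <- NULL
  out
}
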