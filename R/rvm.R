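## Random variance model (empirical-Bayes variance shrinkage).
##
## Per-transcript residual variances s2 with df m are modelled as arising
## from gene-specific variances whose reciprocals follow a Gamma(a, b)
## prior, so that s2 * a * b ~ F(m, 2a). The hyperparameters are fitted by
## maximum likelihood across transcripts; the shrunken variance is the
## df-weighted combination of the observed variance (weight m) and the
## prior mean 1/(a b) (weight 2a), and moderated F-tests gain 2a residual
## degrees of freedom.

#' Fit random variance model hyperparameters
#'
#' Maximizes the scaled-F likelihood of observed residual variances under
#' the random variance model (inverse-variances Gamma(a, b) distributed).
#'
#' @param s2 Per-unit residual variances (must be > 0 to contribute).
#' @param df Residual degrees of freedom, length 1 or `length(s2)`.
#' @return A list with `a`, `b`, the prior mean variance `prior_var`
#'   (= 1/(a*b)) and the achieved log-likelihood.
#' @export
rvm_fit <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2) stopf("need at least two positive variances to fit RVM")
  s2f <- s2[ok]; dff <- df[ok]
  negll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -sum(stats::df(s2f * a * b, dff, 2 * a, log = TRUE) + log(a * b))
  }
  init <- c(log(1), log(1 / stats::median(s2f)))
  fit <- stats::optim(init, negll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  a <- exp(fit$par[1]); b <- exp(fit$par[2])
  list(a = a, b = b, prior_var = 1 / (a * b), loglik = -fit$value)
}

#' Shrink residual variances with a fitted random variance model
#'
#' Returns `(m * s2 + 2a * prior_var) / (m + 2a)` where
#' `prior_var = 1/(a*b)`. As `a` grows the shrunken variance approaches the
#' prior mean; as `a` approaches zero it approaches the observed variance.
#'
#' @param s2 Observed residual variances.
#' @param df Residual degrees of freedom (recycled).
#' @param fit A fit from [rvm_fit()], or a list with `a` and `b`.
#' @return Shrunken variances, same length as `s2`.
#' @export
rvm_shrink <- function(s2, df, fit) {
  df <- rep_len(df, length(s2))
  (df * s2 + 2 * fit$a / (fit$a * fit$b)) / (df + 2 * fit$a)
}
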