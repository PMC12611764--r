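## Synthetic-data generators. Every generator is deterministic given the
## scenario seed and returns a truth table sufficient to score downstream
## detectors (sensitivity / false-discovery proportion).

rdirichlet1 <- function(k, conc) {
  g <- stats::rgamma(k, shape = conc, rate = 1)
  if (sum(g) == 0) g <- rep(1, k)  # degenerate draw at tiny conc
  g / sum(g)
}

#' Simulate a TSS peak count table with planted switching
#'
#' Draws, per transcript, a set of distinct TSS positions (nt upstream of the
#' AUG), Dirichlet baseline isoform proportions shared by both conditions,
#' and negative-binomial tag counts per sample around
#' `mean_depth * lib_factor * proportion`. For a `switch_fraction` of
#' transcripts, `switch_delta` of proportion mass is moved between the
#' 5'-most (longest) and 3'-most (shortest) isoform in the treatment
#' condition, in a per-transcript random direction.
#'
#' @param scenario A [switch_scenario()].
#' @return A list with elements:
#' \describe{
#'   \item{counts}{data.frame `transcript_id`, `position` (nt upstream of
#'     AUG), one integer count column per sample.}
#'   \item{design}{data.frame `sample`, `condition` (`control`/`treatment`),
#'     `replicate`.}
#'   \item{truth}{per-transcript data.frame with `switched`, `delta`,
#'     `direction` (`lengthen`/`shorten`), donor/acceptor positions.}
#'   \item{isoforms}{per-isoform data.frame of true proportions per
#'     condition.}
#' }
#' @export
simulate_tss_counts <- function(scenario) {
  stopifnot(inherits(scenario, "switch_scenario"))
  s <- scenario
  set.seed(s$seed)

  reps <- s$reps_per_condition
  conditions <- c(rep("control", reps[1]), rep("treatment", reps[2]))
  replicate <- c(seq_len(reps[1]), seq_len(reps[2]))
  samples <- paste0(ifelse(conditions == "control", "ctrl_", "treat_"),
                    replicate)
  design <- data.frame(sample = samples, condition = conditions,
                       replicate = as.character(replicate),
                       stringsAsFactors = FALSE)
  lib <- s$lib_size_factors
  if (is.null(lib)) lib <- stats::runif(length(samples), 0.5, 1.5)

  n_switch <- round(s$switch_fraction * s$n_transcripts)
  switched <- rep(FALSE, s$n_transcripts)
  if (n_switch > 0)
    switched[sample.int(s$n_transcripts, n_switch)] <- TRUE

  counts_list <- vector("list", s$n_transcripts)
  iso_list <- vector("list", s$n_transcripts)
  truth <- data.frame(transcript_id = sprintf("tx%05d", seq_len(s$n_transcripts)),
                      switched = switched, delta = 0, direction = NA_character_,
                      donor_position = NA_integer_,
                      acceptor_position = NA_integer_,
                      stringsAsFactors = FALSE)

  for (t in seq_len(s$n_transcripts)) {
    k_rng <- s$isoforms_per_transcript
    k <- if (k_rng[1] == k_rng[2]) k_rng[1] else
      sample(seq(k_rng[1], k_rng[2]), 1L)
    L <- if (s$utr_length_range[1] == s$utr_length_range[2])
      s$utr_length_range[1] else
      sample(seq(s$utr_length_range[1], s$utr_length_range[2]), 1L)
    grid <- seq(1L, L, by = s$min_spacing)
    if (length(grid) < k) grid <- seq_len(k) * s$min_spacing
    pos <- sort(sample(grid, k))

    p_ctrl <- rdirichlet1(k, s$baseline_conc)
    p_treat <- p_ctrl
    if (switched[t] && k >= 2) {
      # move mass between the 3'-most (smallest position, shortest 5'UTR)
      # and 5'-most (largest position, longest 5'UTR) isoform
      lengthen <- stats::runif(1) < 0.5
      from <- if (lengthen) 1L else k
      to <- if (lengthen) k else 1L
      tries <- 0L
      while (p_ctrl[from] < s$switch_delta + 0.02 && tries < 200L) {
        p_ctrl <- rdirichlet1(k, s$baseline_conc)
        tries <- tries + 1L
      }
      if (p_ctrl[from] < s$switch_delta + 0.02) {
        p_ctrl[from] <- s$switch_delta + 0.05
        p_ctrl[-from] <- p_ctrl[-from] / sum(p_ctrl[-from]) *
          (1 - p_ctrl[from])
      }
      p_treat <- p_ctrl
      p_treat[from] <- p_treat[from] - s$switch_delta
      p_treat[to] <- p_treat[to] + s$switch_delta
      truth$delta[t] <- s$switch_delta
      truth$direction[t] <- if (lengthen) "lengthen" else "shorten"
      truth$donor_position[t] <- pos[from]
      truth$acceptor_position[t] <- pos[to]
    }

    mat <- matrix(0L, nrow = k, ncol = length(samples))
    for (j in seq_along(samples)) {
      p <- if (conditions[j] == "control") p_ctrl else p_treat
      mu <- s$mean_depth * lib[j] * p
      mat[, j] <- stats::rnbinom(k, mu = mu, size = s$dispersion)
    }
    colnames(mat) <- samples
    counts_list[[t]] <- data.frame(transcript_id = truth$transcript_id[t],
                                   position = pos, mat,
                                   stringsAsFactors = FALSE,
                                   check.names = FALSE)
    iso_list[[t]] <- data.frame(transcript_id = truth$transcript_id[t],
                                position = pos, prop_control = p_ctrl,
                                prop_treatment = p_treat,
                                stringsAsFactors = FALSE)
  }

  list(counts = do.call(rbind, counts_list),
       design = design,
       truth = truth,
       isoforms = do.call(rbind, iso_list))
}

#' Simulate histone-mark coverage profiles around TSSs
#'
#' Per region, expected coverage is a Gaussian bump plus uniform background,
#' binned over the region span; observed coverage adds Poisson noise per
#' replicate. Shifted regions have the treatment bump centre displaced by
#' `planted_shift` nt; broadened regions have the treatment bump SD
#' multiplied by `broaden_factor` with the centre fixed.
#'
#' @param scenario A [coverage_scenario()].
#' @return A list with elements `offsets` (bin start positions, nt relative
#'   to the TSS), `coverage` (list with `control` and `treatment`, each an
#'   array regions x bins x replicates), `control_input` (matrix regions x
#'   bins of background-only input coverage) and `truth` (data.frame with
#'   per-region `class` in `none`/`shift`/`broaden`, `shift`, `centre`).
#' @export
simulate_chip_coverage <- function(scenario) {
  stopifnot(inherits(scenario, "coverage_scenario"))
  s <- scenario
  set.seed(s$seed)

  offsets <- seq(s$region_span[1], s$region_span[2] - 1L, by = s$bin_width)
  nb <- length(offsets)
  mid <- offsets + s$bin_width / 2
  span <- diff(s$region_span)

  cls <- rep("none", s$n_regions)
  if (s$n_shifted > 0) cls[seq_len(s$n_shifted)] <- "shift"
  if (s$n_broadened > 0)
    cls[s$n_shifted + seq_len(s$n_broadened)] <- "broaden"
  cls <- sample(cls)  # random assignment of region identities
  centre <- stats::runif(s$n_regions, 0, 1000)

  expected <- function(c0, width) {
    dens <- (1 - s$background_level) * stats::dnorm(mid, c0, width) +
      s$background_level / span
    s$mean_depth * dens * s$bin_width
  }

  cov <- list(
    control = array(0, dim = c(s$n_regions, nb, s$reps)),
    treatment = array(0, dim = c(s$n_regions, nb, s$reps)))
  for (r in seq_len(s$n_regions)) {
    mu_a <- expected(centre[r], s$peak_width)
    c_b <- centre[r] + if (cls[r] == "shift") s$planted_shift else 0
    w_b <- s$peak_width * if (cls[r] == "broaden") s$broaden_factor else 1
    mu_b <- expected(c_b, w_b)
    for (j in seq_len(s$reps)) {
      cov$control[r, , j] <- stats::rpois(nb, mu_a)
      cov$treatment[r, , j] <- stats::rpois(nb, mu_b)
    }
  }

  control_input <- matrix(
    stats::rpois(s$n_regions * nb, s$mean_depth * s$bin_width / span),
    nrow = s$n_regions)

  truth <- data.frame(region_id = sprintf("region%04d", seq_len(s$n_regions)),
                      class = cls,
                      shift = ifelse(cls == "shift", s$planted_shift, 0),
                      centre = centre, stringsAsFactors = FALSE)
  list(offsets = offsets, coverage = cov, control_input = control_input,
       truth = truth)
}

#' Simulate a per-gene regulation vector with a linear feature structure
#'
#' Generates a feature matrix with correlated continuous columns and binary
#' signature columns, and a regulation vector that is a linear combination
#' of features plus Gaussian noise. The truth records the coefficients and
#' the implied population unique percentage of variance per feature
#' (semi-partial R-squared), computed analytically from the population
#' covariance.
#'
#' @param n_genes Number of genes.
#' @param betas Named numeric vector of effects, one per feature; names
#'   define the feature columns.
#' @param binary Character vector naming which features are 0/1 signature
#'   columns (prevalence 0.3); the rest are standard normal.
#' @param collinearity Equicorrelation among continuous features; must have
#'   absolute value < 1.
#' @param noise_sd Gaussian noise SD added to the linear predictor.
#' @param seed Integer seed.
#' @return A list `y` (numeric regulation vector), `X` (data.frame of
#'   features) and `truth` (betas, per-feature unique percent variance,
#'   total explained percent variance).
#' @export
simulate_feature_table <- function(n_genes, betas, binary = character(),
                                   collinearity = 0, noise_sd = 1,
                                   seed = 1L) {
  if (is.null(names(betas)) || any(names(betas) == ""))
    stopf("betas must be a fully named vector")
  if (abs(collinearity) >= 1)
    stopf("|collinearity| must be < 1")
  if (!all(binary %in% names(betas)))
    stopf("binary names must be a subset of names(betas)")
  set.seed(as.integer(seed))

  feats <- names(betas)
  cont <- setdiff(feats, binary)
  X <- matrix(0, n_genes, length(feats), dimnames = list(NULL, feats))
  if (length(cont) > 0) {
    z0 <- stats::rnorm(n_genes)
    for (f in cont)
      X[, f] <- sqrt(abs(collinearity)) * z0 * sign(collinearity) ^
        (match(f, cont) - 1) +
        sqrt(1 - abs(collinearity)) * stats::rnorm(n_genes)
  }
  for (f in binary) X[, f] <- stats::rbinom(n_genes, 1L, 0.3)

  y <- drop(X %*% betas) + stats::rnorm(n_genes, sd = noise_sd)

  # population covariance for the analytic variance decomposition
  p_bin <- 0.3
  Sigma <- diag(length(feats))
  dimnames(Sigma) <- list(feats, feats)
  if (length(cont) > 1) {
    for (i in cont) for (j in cont) if (i != j) {
      sgn <- sign(collinearity) ^ (match(i, cont) + match(j, cont) - 2)
      Sigma[i, j] <- abs(collinearity) * sgn
    }
  }
  for (f in binary) Sigma[f, f] <- p_bin * (1 - p_bin)
  var_y <- drop(t(betas) %*% Sigma %*% betas) + noise_sd^2
  r2_with <- function(set) {
    if (length(set) == 0) return(0)
    cyx <- Sigma[set, , drop = FALSE] %*% betas
    drop(t(cyx) %*% solve(Sigma[set, set, drop = FALSE]) %*% cyx) / var_y
  }
  r2_full <- r2_with(feats)
  unique_pct <- vapply(feats, function(f)
    100 * (r2_full - r2_with(setdiff(feats, f))), numeric(1))

  list(y = y, X = as.data.frame(X),
       truth = list(betas = betas, unique_pct = unique_pct,
                    total_pct = 100 * r2_full, noise_sd = noise_sd))
}
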