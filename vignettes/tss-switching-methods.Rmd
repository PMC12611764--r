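---
title: "Methods: detecting and modelling TSS switching from 5'-end counts"
author: "tsswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and modelling TSS switching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsswitch)
```

## The problem

5′-end sequencing (CAGE-like protocols) marks transcription start sites at
single-nucleotide resolution: each read's 5′ end is a TSS observation,
recorded here as a position in nt upstream of the annotated start codon.
Most protein-coding transcripts express several TSS clusters — distinct
5′UTR isoforms — and conditions such as hypoxia or pharmacological
perturbation of H3K4me3 shift the *relative* usage of those clusters
without necessarily changing total mRNA. Because 5′UTR content (length,
GC, secondary structure, uORFs, TOP motifs) governs translation
initiation, such switching re-programs protein synthesis silently with
respect to ordinary differential expression analysis. `tsswitch`
implements the detection of switching, its quantitative scoring, and two
downstream analyses: variance-partition modelling of translational
regulation against 5′UTR features, and classification of positional
shifts in histone-mark coverage around TSSs.

## Quantification of 5′UTR isoforms

**Reproducibility filter.** A peak is *detected* in a sample when its
count exceeds zero; no minimum-count threshold is imposed. The lenient
rule keeps a peak detected in at least *n* − 1 replicates of at least one
condition; the strict rule (appropriate for deeper libraries with more
spurious positions) requires all replicates of a condition. Transcripts
whose retained peaks sum to fewer than 10 reads across all samples are
dropped. The read-count filter runs *after* the reproducibility filter, so
a transcript is judged on the evidence that survives replication; the
alternative order would let irreproducible singletons rescue a transcript.

**Normalization.** Tags per million per sample
(`count / sample total × 10⁶`). All downstream proportion-based statistics
are invariant to library size by construction.

**Low-expression filter.** Within a transcript, a peak whose cross-sample
mean TPM falls below 25% of the transcript's mean peak TPM is removed.
"Mean TPM per transcript" is read as the mean over peaks of each peak's
cross-sample mean — a replicate-balanced summary. The alternative
(per-sample means) is a one-line change in
`filter_low_expression_peaks()`.

**Clustering.** Clusters start at the first (most AUG-proximal) peak and
extend while the next peak lies within the window of the **last included
peak** (a chain rule, matching "extended until there were no peaks within
the window"), with the window at 5 nt, or `ceiling(0.025 × longest
isoform length)` when the longest isoform exceeds 200 nt (ceiling keeps
integer nt; the rounding direction is otherwise unspecified). Positions
are integers; intervals are half-open `[lo, hi)`. Clusters are built per
condition — positions absent from one condition would otherwise fragment
shared clusters — and unified across conditions by interval union, with
abutting intervals merged.

## The three-arm switching test

Isoforms are routed by their detection pattern: *quantitative* (detected
in every sample of both conditions), *fisher* (≥ 2 replicates per
condition but not all samples), *unique* (exactly one condition), or
*untestable* (e.g. one replicate in one condition alongside detections in
the other — a cell the three rules leave undefined, reported as such).
Quantitative isoforms in transcripts with fewer than two such isoforms
cannot support an interaction model; they satisfy the Fisher arm's
detection requirement by construction and are tested there.

**Quantitative arm.** Cluster counts are transformed to log2 counts per
million with precision weights from the fitted mean–variance trend
(limma's voom), estimated once across all quantitative isoforms jointly.
Per transcript, weighted least squares fits
`expression ~ isoform + condition + replicate + isoform:condition`; a low
interaction p-value indicates isoform usage depends on condition
independently of overall expression and replicate effects. Residual
variances are then moderated by a random variance model: inverse
variances are assumed Gamma(a, b), so observed variances follow a scaled
F distribution (`s² a b ~ F(m, 2a)`); (a, b) are fitted by maximum
likelihood over all tested transcripts, and the moderated variance is the
degrees-of-freedom-weighted mix `(m s² + 2a/(ab)) / (m + 2a)` with the
interaction F on `(q − 1, m + 2a)` degrees of freedom. The voom weights
are propagated into the moderated F (disable with `use_weights = FALSE`).
With fewer than 50 tested transcripts the hyperparameter fit is unstable
and the unmoderated F is used. Numerically perfect fits (noiseless data)
are resolved on unweighted residuals, since precision weights diverge at
zero estimated variance: no interaction signal means F = 0.

**Fisher arm.** Per isoform: a two-sided exact test on the 2×2 table of
condition-summed reads, isoform versus all other isoforms of its
transcript. Results are reported per isoform (a transcript can switch in
one isoform only); a table with an empty margin is uninformative (p = 1).

**Unique arm.** For an isoform seen in only one condition,
`p = (r_si / (r_ui + r_si))^r_sj`: the probability, under the expressing
condition's isoform proportions, that all reads in the other condition
come from shared isoforms. It is 1 at `r_sj = 0` (no evidence) and 0 when
the expressing condition has no shared reads.

All arm p-values are pooled into one Benjamini–Hochberg adjustment
(stable (p, id) ordering for reproducibility) with significance at
FDR < 0.15.

## Change-point scoring

Replicate-mean TPM per condition is accumulated over positions in
ascending nt-upstream order — from the AUG outward — and normalized to a
cumulative share, so the treatment−control difference starts and ends at
zero and its plateaus mark differentially used regions. The "short"
segment is therefore the region nearest the start codon. Change points in
the difference vector are found by an exact segment-neighbourhood dynamic
programme (minimal within-segment sum of squares for 1–3 segments; at
most 2 change points, as the segmentation targets short/middle/long
regions). The segment count is chosen by AIC under a Gaussian mean-change
likelihood whose variance is pooled over the whole vector — a single
variance makes the likelihoods comparable across segment counts — with a
penalty of 2 per change point on the −2 log-likelihood scale; a constant
vector yields no change points. Transcripts with only two positions get
the single admissible boundary directly. Change points are computed on
replicate means, consistent with the replicate-mean usage elsewhere in
the pipeline.

Per-segment enrichment is the difference in each segment's share of total
expression (percentage points; the deltas sum to zero). The TSS-switch
score defaults to the **range** of the deltas: with two segments the
deltas are ±Δ and the score is 2Δ, which is the only reading that
reconciles a ~20-percentage-point segment enrichment with a score of ~50
for the same transcript; `mode = "maxabs"` is available. Scores can be
computed for all transcripts (as a covariate) or restricted to
significant switchers. Categories label the segments enriched beyond a
1-percentage-point dead zone (e.g. "short", "long", "short+long",
"none"); the same dead zone defines the sign patterns used by the
concordance module, which requires a shared threshold to make signs
well-defined.

## Cross-treatment concordance

Two comparisons are *equivalent* on a transcript when every segment's
sign matches, and *reversed* when nonzero signs are all opposite and
zeros match (all-zero patterns are neither; the two relations are
mutually exclusive for patterns with at least one nonzero sign). The
chance level of concordance is estimated by permuting one comparison's
patterns across transcripts — a permutation null preserves both marginal
category frequency tables and makes no distributional assumptions — and
agrees with the closed form `Σ_c f_A(c) f_B(c)`. The FDR trend uses
equal-count ventiles (quantile bins) rather than equal-width bins because
FDR distributions are heavily skewed; the per-bin proportion of
concordant transcripts and the slope over bins are reported.

## 5′UTR features and postNet

Features are computed per isoform and combined per gene either by the
dominant isoform (most expressed, ties to the longest) or by
expression-weighted means. uORFs are AUGs with an in-frame stop codon
inside the 5′UTR (fully upstream; CDS-overlapping ORFs are a different
regulatory class and are optional). The TOPscore is the
expression-weighted fraction of TSS positions initiating with C followed
by ≥ 4 pyrimidines (a permissive mode accepts U at +1). Motif gain/loss
compares the expression fraction carried by motif-containing isoforms
between conditions against a 10-percentage-point dead zone; "fraction of
expressed isoforms" is read as expression-weighted, with a count-based
mode available. Motifs are IUPAC strings matched as substrings; folding
energy and G-quadruplex calls are imported as precomputed columns.

postNet explains a per-gene regulation vector (e.g. log2 change in
translation efficiency) from feature columns in three steps: (1) a
univariate screen (OLS per feature; a feature must be non-constant on at
least 8 genes to enter — the covariate filter is read as a minimum
non-modal count, and is configurable); (2) forward stepwise selection
seeded by the best univariate feature, adding candidates while the
partial F-test p-value is below 0.05, recording a covariance edge
whenever an included variable absorbs more than 10% shared variance of a
candidate (pairwise `R²_c + R²_u − R²_{cu}`); (3) semi-partial
decomposition: each selected variable's unique percentage of variance is
`100 (R²_full − R²_without)`, with unexplained variance
`100 (1 − R²_full)`. Continuous features are standardized before
selection for comparability; binary signatures stay 0/1. Ties are broken
lexicographically so the result is invariant to column order. The
quartile-bin analysis takes the 400 most up- and downregulated genes,
bins each direction by fold-change quartiles, and compares each bin's
score distribution to the unbinned background by two-sided rank-sum
tests with quantile shifts at q25/q50/q75; when fewer than three times
the bin size is available the tails are shrunk to a third of the genes so
a background always remains.

## Histone-mark shift classification

Per region (TSS − 2 kb to + 10 kb), coverage is accumulated 5′→3′ and
trimmed where 95% of total signal is reached (histone-mark extension
around TSSs is highly variable); within the trimmed region the first
position reaching each 0.1% increment of cumulative signal is recorded —
1,000 positions that summarize the distribution compactly, equivariant to
translation and invariant to scaling. Regions are filtered on a common
scale — coverage divided by the 99th percentile of positive signal values
across regions, mapping strong signal near 1 — keeping regions with
maximum scaled signal ≥ 0.8 and maximum scaled input-control coverage
≤ 0.6. Both thresholds sit on the same axis so "background above 0.6"
means background approaching signal strength; signal strength is judged
on the per-position maximum across conditions, because averaging
conditions would dilute displaced bumps and bias the filter against
exactly the regions under test. Scaling and thresholds are configurable.

The replicate-mean quantile-position vectors of the two conditions are
compared by a two-sided Wilcoxon rank-sum test (mid-ranks for ties), with
direction *downstream*/*upstream* when the q25/q50/q75 position
differences agree in sign, and by a two-sided Kolmogorov–Smirnov test for
non-directional change. Each test family is Benjamini–Hochberg adjusted;
at FDR < 0.01 a region is labelled by its direction, "other" for a
significant KS without a directional call, else unchanged.

## What the simulators emulate — and what they do not

`simulate_tss_counts` draws per-transcript TSS positions on an integer
grid (minimum spacing 12 nt, above the clustering window so planted
isoforms stay distinct), Dirichlet baseline proportions (concentration 5:
moderately uneven usage), negative-binomial counts (size 10, matching
overdispersed 5′-end tag counts) around `depth × library factor ×
proportion`, and library-size factors uniform in 0.5–1.5. Planted
switches move a fixed proportion (default 0.3) between the 5′-most and
3′-most isoforms — mirroring the shortest/longest enrichment categories —
in a random direction per transcript; defaults of 3v3 replicates and
depth 100 represent a realistic two-condition 5′-end experiment.
`simulate_chip_coverage` lays a Gaussian bump (SD 300 nt) plus uniform
background and Poisson noise over −2 kb..+10 kb, with planted centre
displacement or symmetric broadening; coverage is binned at 10 nt by
default — planted shifts of hundreds of nt are far above this
resolution — with 1-nt bins available for single-nt checks.
`simulate_feature_table` produces equicorrelated Gaussian features,
binary signatures (prevalence 0.3) and a linear response, with the
implied unique variance fractions computed analytically from the
population covariance.

None of the generators model UMI artefacts, strand invasion, positional
biases along the UTR, mappability, or non-linear feature effects. Passing
tests therefore demonstrate the statistical machinery is correct and
calibrated under the assumed generative structure; they do not certify
performance on real libraries, where the filters exist precisely to
absorb violations of those assumptions.

## Numerical and design choices

- Detection is `count > 0`; AIC penalty 2 per change point; BH ties
  broken by (p, id); ventiles equal-count ± 1.
- The RVM likelihood is maximized over `log(a), log(b)` by Nelder–Mead
  from a moment-style start; shrinkage approaches the observed variance
  as a → 0 and the prior mean as a → ∞ (at fixed prior mean).
- Zero-expression conditions skip a transcript in cumulative profiles
  (reported via an attribute); zero-signal regions are excluded before
  quantile construction; zero-total samples are a hard error naming the
  sample.
- Monte Carlo concordance permutes *patterns* (not change points or raw
  isoform labels): the minimal-assumption null given that only patterns
  are compared.
- The null-calibration, power, recovery and classification checks in the
  test suite run at 2,000 null transcripts, 1,000 transcripts with 20%
  planted switches, 500 planted profiles, and 1,000 coverage regions
  respectively — sizes at which the binomial error of the measured rates
  is well below the margins being asserted.

## Known limitations

- Only two-condition designs are supported; the interaction model, the
  Fisher tables and the unique-isoform probability are all two-sample
  constructs.
- The Fisher arm treats condition-summed reads as independent
  observations; replicate overdispersion is not propagated in that arm.
- The unique-isoform probability is a closed-form screen, not a
  calibrated test; it enters the pooled BH family as the only available
  evidence for condition-exclusive isoforms.
- Wilcoxon/KS on the 1,000 quantile positions treat the points as a
  sample; their serial correlation makes the nominal p-values
  conservative summaries of profile difference rather than exact
  probabilities — the FDR threshold of 0.01 and the quartile-sign
  requirement are what control false directional calls in practice.
- postNet's forward selection inherits the usual stepwise caveats
  (greedy, order-dependent under near-ties in noise); edges are pairwise
  shared-variance summaries, not a full covariance decomposition.
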