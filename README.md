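# tsswitch

Detection, scoring and downstream modelling of **transcription start site
(TSS) switching** from CAGE-like 5′-end sequencing counts.

Genes commonly use several TSSs, producing mRNA isoforms that share a coding
sequence but differ in their 5′UTR. Under stresses such as hypoxia, cells
shift the relative usage of these TSSs ("TSS switching"), remodelling 5′UTR
content — length, GC, uORFs, 5′-terminal oligopyrimidine (TOP) motifs — and
thereby changing how efficiently each mRNA is translated, often without any
change in total mRNA abundance. `tsswitch` implements an end-to-end,
fully testable pipeline for this analysis:

1. **Quantification** (`quantify_tss`): TSS peaks (5′-end tag positions,
   measured in nt upstream of the AUG) are filtered for replicate
   reproducibility (detected in ≥ *n* − 1 replicates of a condition;
   strict mode requires all), normalized to tags per million (TPM),
   cleared of low-expression peaks (< 25% of the transcript's mean peak
   TPM), and clustered into 5′UTR isoforms with a dynamic sliding window
   (5 nt, scaled to 2.5% of the longest isoform beyond 200 nt), unified
   across conditions.
2. **Differential TSS usage** (`test_tss_switching`): a three-arm test.
   Isoforms detected in every sample are tested per transcript with the
   interaction linear model

   `Ex ~ isoform + condition + replicate + isoform:condition`

   on voom-normalized log2 counts per million, with per-transcript residual
   variances moderated by a random variance model (inverse-variance
   Gamma(a, b) prior, fitted by maximum likelihood; the interaction F gains
   2a residual degrees of freedom). Partially detected isoforms are tested
   with Fisher's exact test on condition-summed reads; condition-exclusive
   isoforms with the unique-isoform probability
   `p = (r_s / (r_u + r_s))^r_s'`. All p-values are pooled under
   Benjamini–Hochberg; switching is called at FDR < 0.15.
3. **Change-point scoring** (`score_tss_switching`): the difference in
   cumulative isoform expression (treatment − control, accumulated from
   the AUG outward) is segmented by an exact segment-neighbourhood search
   (≤ 2 change points, AIC-selected); per-segment enrichment deltas (in
   percentage points) yield the **TSS-switch score** (range of deltas) and
   a short/middle/long category.
4. **Cross-treatment concordance** (`pattern_equivalence`,
   `monte_carlo_chance`, `ventile_trend`): equivalent and reversed
   switching patterns between two comparisons, the chance expectation by
   permutation Monte Carlo, and the concordance trend over FDR ventiles.
5. **5′UTR features** (`count_uorfs`, `top_score`,
   `motif_occupancy_change`, …) and **postNet variance-partition
   modelling** (`postnet`): univariate screen → forward stepwise selection
   with covariance edges → semi-partial percentage of variance per
   selected feature, plus the quartile-bin ECDF shift analysis
   (`ecdf_bin_shift`).
6. **Histone-mark shift classification** (`classify_shift`): coverage
   around TSSs is summarized as 1,000 cumulative-quantile positions
   (trimmed at 95% of signal), filtered on scaled signal/background
   (≥ 0.8 / ≤ 0.6), and classified as downstream / upstream / other via
   Wilcoxon rank-sum with quartile directionality and Kolmogorov–Smirnov
   tests at FDR < 0.01.

A synthetic-data module (`switch_scenario` / `simulate_tss_counts`,
`coverage_scenario` / `simulate_chip_coverage`, `simulate_feature_table`)
generates inputs with the statistical structure the analysis assumes —
Dirichlet isoform proportions with planted condition-dependent shifts,
negative-binomial replicate noise, unequal library sizes, Gaussian coverage
bumps with planted displacement — together with truth tables, so every
stage can be benchmarked without external data.

## Worked example

```r
library(tsswitch)

sc  <- switch_scenario(n_transcripts = 300, switch_fraction = 0.2,
                       switch_delta = 0.3, mean_depth = 100, seed = 42)
sim <- simulate_tss_counts(sc)
res <- run_pipeline(sim$counts, sim$design, "treatment", "control")
print(res$test)
head(res$scores, 5)
```

```
Differential TSS usage test (three-arm, BH-pooled)
  303 tested units over 300 transcripts
arm
      fisher quantitative 
           3          300 
  64 transcripts significant at FDR < 0.15
  transcript_id cp1 cp2 delta_short delta_middle delta_long    score category
1       tx00003  97  NA   -38.99592           NA   38.99592 77.99184     long
2       tx00004 253  NA   -22.14781           NA   22.14781 44.29562     long
3       tx00005 109  NA   -39.71148           NA   39.71148 79.42296     long
4       tx00016 217  NA    37.21987           NA  -37.21987 74.43973    short
5       tx00020 145  NA    44.54706           NA  -44.54706 89.09412    short
```

300 simulated transcripts, 60 of which carry a planted 0.3 shift in
isoform proportions, give 64 significant calls. `cp1` is the change-point
position in nt upstream of the AUG; `delta_short`/`delta_long` are the
percentage-point enrichment of the 5′UTR segments nearest to and furthest
from the start codon (a `long` category means longer 5′UTRs are enriched
under treatment); `score` is the spread of the deltas. Against the
simulator's truth table this run attains sensitivity 0.92 at an observed
false-discovery proportion of 0.14 (nominal FDR 0.15).

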