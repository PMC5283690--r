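# mranet

Master-regulator analysis over multi-cohort coexpression networks.

`mranet` is for computational biologists who have (i) a two-condition
perturbation experiment defining a transcriptional signature — e.g. an
isogenic cell line with an inducible oncogene such as mutant *KRAS* — and
(ii) a collection of tumour expression cohorts, and who want to know which
transcription factors (TFs) drive that signature, how those regulators
group into biological processes, and what the activity of those processes
means for patients. The package implements the full workflow as composable
R functions, plus a synthetic-data generator with planted ground truth
that makes every stage testable.

## The method

1. **Signature** — per-gene moderated t-statistics with empirical-Bayes
   variance shrinkage: posterior variance
   `s~² = (d₀s₀² + d_g s_g²)/(d₀ + d_g)` with the prior `(d₀, s₀²)`
   moment-matched on the log variances; cross-species ortholog mapping and
   `p < 0.05, |log2FC| > 1` thresholding for reporting.
2. **Per-cohort networks** — Schäfer–Strimmer shrinkage partial
   correlations between regulators and all genes
   (`λ* = Σ V̂ar(r_ij) / Σ r_ij²`, `pcor = -ω_ij/√(ω_ii ω_jj)`), an
   MAD-based empirical null on the Fisher-z scale, and BH q-values. A
   TF's **regulon** is its set of targets at `q < 0.05`, each with a mode
   of regulation (sign) and likelihood weight `1 - q`.
3. **Fusion** — size-weighted Stouffer combination across cohorts,
   `Z = Σ √n_i z_i / √(Σ n_i)`, keeping edges measured in ≥ 4 cohorts; BH
   once over the fused network.
4. **Master regulators** — aREA-style regulon enrichment in the ranked
   signature: `ES = Σ w_j m_j Φ⁻¹(rank_j/(N+1)) / √(Σ w_j²)` with a
   standard-normal null (a gene-label permutation oracle is included);
   MRs are TFs with `p < 0.01`. Clauset–Newman–Moore greedy modularity on
   the MR–target graph groups MRs into core processes.
5. **Subtypes & characterization** — per-sample MR activities (the same
   enrichment score on each sample's z-score profile), `1 - Pearson`
   signature distance, average-linkage clustering into k = 3 subtypes;
   then Kaplan–Meier / log-rank / Cox (Efron ties) survival comparison,
   mutational-burden ANOVA with HIGH/MODERATE-impact, loss (≤ -1) and
   amplification (> 5 copies) filters, ssGSEA (rank-weighted running sum,
   α = 0.25), stromal/immune admixture scores, NNLS deconvolution with a
   1,000-permutation significance test, first-order partial correlations
   with multiply-by-m correction, and hypergeometric label-overlap tests.

## Worked example

Simulate a study at the scale the package targets — 55 TFs with 27
planted master regulators in three communities, seven cohorts of
242/178/36/36/26/25/17 samples, a 6-vs-6 perturbation — and run the whole
pipeline:

```r
library(mranet)
study <- simulateStudy(seed = 1)
res   <- runPipeline(study)
head(res$mrTable)
#>      tf       nes            p            q size is_mr
#> 1 TF015 -6.382911 1.737526e-10 9.556394e-09   51  TRUE
#> 2 TF018 -6.211838 5.236853e-10 1.440135e-08   59  TRUE
#> 3 TF010  5.864659 4.500564e-09 8.251033e-08   57  TRUE
#> 4 TF019  5.711202 1.121811e-08 1.542490e-07   49  TRUE
#> 5 TF022  5.643524 1.666047e-08 1.832651e-07   54  TRUE
#> 6 TF004  5.390641 7.020687e-08 6.435630e-07   50  TRUE
```

Each row is a TF: `nes` is the normalized enrichment of its regulon in the
perturbation signature (sign = inferred direction of its activity change),
and `is_mr` flags master regulators at p < 0.01. Compare with the planted
truth:

```r
evaluateRecovery(res)[c("recovered", "falsePositives",
                        "communityAri", "subtypeAri")]
#> $recovered       [1] 27        # all 27 planted MRs flagged
#> $falsePositives  [1] 0
#> $communityAri    [1] 1         # three core processes exactly recovered
#> $subtypeAri      [1] 0.9786712 # sample subtypes vs planted labels
```

Survival characterization of the discovered subtypes (planted hazard
ratios were 1.73 and 0.62 against the reference subtype):

```r
matched <- matchSubtypesToTruth(res$subtypes, truthTable(study))
coxPH(clinicalTable(study), matched, ref = 1)$table
#>   subtype        hr  ci_lower  ci_upper            p
#> 1       2 1.8484633 1.4279431 2.3928242 3.087059e-06
#> 2       3 0.6818488 0.5261874 0.8835595 3.776612e-03
```

The estimated hazard ratios (1.85, 0.68) bracket the planted values within
sampling error at n = 560 with ~30% censoring.

See the vignette (`vignettes/master-regulator-workflow.Rmd`) for the
model, every tunable parameter, and the design decisions.

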