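# admixcor

Individual admixture proportions and their cardio-metabolic correlates.

`admixcor` is an R package for the analysis chain that links genetic
ancestry to a quantitative cardio-metabolic trait in a two-way admixed
cohort.  It was built around the association between the individual
*proportion of European ancestry* (PEA) and plasma adiponectin in an
African-American population sample, but every stage is generic:

1. **Ancestry estimation** (`estimate_ancestry`, `estimate_cohort`) —
   maximum-likelihood estimation of each individual's admixture
   proportion from a panel of ancestry-informative markers (AIMs).
   With ancestral counted-allele frequencies `p_afr`, `p_eur` and
   dosage `G_i ~ Binomial(2, p_i(s))` at the admixed frequency
   `p_i(s) = s·p_eur + (1−s)·p_afr`, the estimator maximizes
   `Σ_i log Pr(G_i | s)` over `s ∈ [0, 1]` (grid scan + bounded
   refinement), with observed-information standard errors and a
   flat-prior posterior-mean alternate estimator for agreement checks.
2. **AIM handling** (`aim_panel`, `select_aims`,
   `read_frequency_table`, `read_genotypes`) — panel validation,
   frequency clamping, and selection by allele-frequency differential
   `δ = |p_afr − p_eur|`.
3. **Phenotype derivation** (`derive_cohort` and friends) — BMI,
   obesity (BMI ≥ 30), HOMA-IR (`insulin × glucose[mmol/L] / 22.5`),
   upper-quartile insulin resistance, diabetes (glucose ≥ 7.0 mmol/L or
   treatment), natural-log adiponectin.
4. **Association statistics** (`sex_difference_table`,
   `adjusted_pearson`, `interaction_lrt`, `stepwise_forward`,
   `stratified_analysis`) — descriptive sex comparisons, age- and
   sex-adjusted Pearson correlations, likelihood-ratio tests of effect
   modification, and forward-stepwise linear models of log-adiponectin
   on PEA within obesity / insulin-resistance strata (entry at
   P ≤ 0.05, exposure always reported).
5. **Spline linearity tests** (`fit_pea_spline`) — penalized cubic
   regression splines (mgcv, GCV) with the compound non-linearity rule:
   significant deviance gain beyond a linear term *and* estimated
   degrees of freedom > 3.
6. **Synthetic cohort generator** (`simulate_cohort`) — admixed
   genotypes and a correlated phenotype table calibrated to the study
   conditions (median PEA 15.8%, IQR 9.3%, stratum-specific ancestry
   effects 0.62 / 0.74), so the whole pipeline is testable end to end
   without any data access.

`run_pipeline()` ties the stages into one seeded, config-driven run that
writes every stage output (ancestry CSV, derived cohort, descriptive /
correlation / regression / interaction tables, spline fits and plots)
plus a JSON report.

## Worked example

```r
library(admixcor)
cohort <- simulate_cohort(sim_config(n_individuals = 400,
                                     n_markers = 600, seed = 42))
est <- estimate_cohort(cohort$genotypes, cohort$panel, min_markers = 100)
round(attr(est, "summary"), 4)
#> median    iqr   mean     sd
#> 0.1638 0.0985 0.1683 0.0784
head(est, 3)
#>   individual_id      s_hat         se    loglik n_used flags
#>       ind_00001 0.15333614 0.03208431 -534.9703    584
#>       ind_00002 0.03403866 0.02891487 -508.1262    589
#>       ind_00003 0.14356235 0.03163891 -526.2355    586
```

Each row is one individual's maximum-likelihood European-ancestry
proportion with its observed-information standard error and the number
of non-missing markers used; the cohort summary shows the generator's
calibrated ancestry distribution (median ≈ 0.16) coming back out of the
genotypes.  At 600 markers the per-individual SE is ≈ 0.03, and the
estimates correlate 0.91 with the generating truth.

```r
d <- derive_cohort(cohort$phenotypes, est)
stratified_analysis(d, strata = "obesity")
#>     stratum   n pea_selected pea_beta pea_se  pea_p    r2        selected
#>   non_obese 141        FALSE   1.0829  0.573 0.0609 0.205 sex+hdl+homa_ir
#>       obese 195        FALSE  -0.0453  0.438 0.9177 0.334 homa_ir+crp+hdl+waist+age
```

The stepwise model reports the ancestry exposure in every stratum even
when it is not selected (here a 400-person cohort is underpowered for
the non-obese effect: the point estimate is positive with p = 0.06,
while the obese stratum is null, as generated).  The spline stage then
asks whether the non-obese relation is a straight line:

```r
fit_pea_spline(d[!d$obese, ], covariates = c("age", "sex"),
               stratum = "non_obese")
#> cubic-spline fit [non_obese]: n = 169, edf = 1.00
#>   deviance 46.22 (with) vs 46.86 (without), p = 0.1329
#>   non-linearity p = 1 -> linear
```

An estimated degrees of freedom of 1 means the penalized smooth
collapsed onto the linear fit: no evidence of curvature.

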