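---
title: "Estimating individual admixture and its cardio-metabolic correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating individual admixture and its cardio-metabolic correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixcor)
```

## The problem

African-American cohorts are two-way admixed: each genome is a mosaic of
African and European ancestral segments, and the genome-wide *proportion of
European ancestry* (PEA) varies from person to person.  When a trait — here
plasma adiponectin, an adipokine inversely related to adiposity and insulin
resistance — differs in prevalence or level between the ancestral
populations, the individual admixture proportion becomes an exposure worth
modelling in its own right.  `admixcor` implements that full chain of
analysis: estimating PEA per individual from a panel of
ancestry-informative markers (AIMs), deriving the cardio-metabolic
variables an epidemiological analysis needs, and testing how, where and in
what shape PEA relates to log-adiponectin.

## The admixture likelihood

An AIM panel stores, for each marker $i$, the frequency of a counted allele
in the two ancestral reference populations: $p_{A,i}$ (African) and
$p_{E,i}$ (European).  For an individual with European ancestry proportion
$s \in [0, 1]$, the counted allele has admixed frequency

$$p_i(s) = s\,p_{E,i} + (1 - s)\,p_{A,i},$$

and under Hardy–Weinberg proportions at that frequency the genotype dosage
$G_i \in \{0, 1, 2\}$ is Binomial$(2, p_i(s))$.  Assuming independence
across loci, the likelihood of one individual's genotypes is
$L(s) = \prod_i \Pr(G_i \mid s)$, and the package maximizes its natural
logarithm $\sum_i \log \Pr(G_i \mid s)$ over $[0, 1]$.  This is the
classical one-parameter maximum-likelihood formulation of individual
admixture; the Hardy–Weinberg genotype model is the simplest model
consistent with it and is the one behind the standard MLE admixture
programs.  Missing genotypes are skipped (the product runs over observed
loci only) and the count of markers used is reported per individual.

Numerical choices:

* **Clamping.** Reference frequencies are clamped to
  $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 0.001$ by default;
  pseudo-ancestral panels contain fixed differences that would otherwise
  put $-\infty$ into the log-likelihood.
* **Optimizer.** A 101-point grid scan brackets the optimum, then bounded
  derivative-free refinement (`stats::optimize`, tolerance $10^{-6}$)
  polishes it; both boundaries are always evaluated explicitly, and among
  candidates within tolerance of the maximum the smallest $s$ wins.  On
  simulated individuals the refined estimate agrees with a 10,000-point
  grid argmax to $10^{-4}$.
* **Standard errors.** From the observed information — the negative
  numerical second derivative at the maximum (step $10^{-4}$) — at interior
  optima; boundary estimates are flagged and carry no SE.
* **Degenerate panels.** If every marker has $p_{A} = p_{E}$ the
  likelihood is flat: the estimate is set to $0.5$ with a
  `non_identifiable` flag rather than erroring, so cohort pipelines keep
  running.

A flat-prior posterior mean, $\int s L(s)\,ds / \int L(s)\,ds$ computed on
a grid in log space with max-subtraction, serves as an independent
alternate estimator; on dense panels the two estimators correlate above
0.99, the cross-method agreement reported for MLE versus the MCMC-based
admixture programs.

The expected (Fisher) information
$I(s) = \sum_i 2 d_i^2 / (p_i(s)(1 - p_i(s)))$ with
$d_i = p_{E,i} - p_{A,i}$ gives the theoretical standard error
`theoretical_ancestry_se()`, the oracle used in the recovery checks:
at the default study scale (1439 individuals × 1447 AIMs, mean
differential 0.4) the cohort RMSE of the estimates sits within a few
percent of the information bound (ratio ≈ 1.02).

## Derived cardio-metabolic variables

The derivation stage applies the standard definitions, with inclusive
boundaries exactly where the definitions put them:

* **BMI** = weight (kg) / height (m)²; **obesity**: BMI ≥ 30.
* **HOMA-IR** = fasting insulin (µU/mL) × fasting glucose (mmol/L) / 22.5.
  Glucose in mg/dL is converted by /18.016.  Units are *declared*, never
  auto-detected — silent unit inference is a correctness hazard.
* **Insulin resistance**: the upper quartile of the non-missing HOMA-IR
  distribution, by average rank — individuals with rank $> 0.75\,n$ are
  flagged.  This rank rule is deterministic under ties, flags exactly 298
  of 1190 distinct values, and flags nobody in a fully tied distribution.
  The quartile is computed on all non-missing values pooled (not by sex,
  not after other exclusions).
* **Diabetes**: fasting glucose ≥ 7.0 mmol/L or anti-diabetic treatment,
  with ordinary three-valued missing-data logic.
* **log-adiponectin**: the natural logarithm.  Coefficient magnitudes on a
  0–1 ancestry predictor are only consistent with natural-log scaling.

Missing insulin leaves HOMA-IR and the IR flag missing; those individuals
simply drop out of IR-stratified models, mirroring the complete-case
convention of the analysis.  No imputation is attempted.

## Association analysis

* **Descriptive sex differences** use the classical equal-variance Student
  t-test (a Welch option exists behind a flag) and the chi-square test
  without continuity correction.
* **Adjusted correlations** residualize both variables on the adjusters
  (age and sex by default) by OLS and correlate the residuals; the
  p-value uses $t = r\sqrt{(n-2-k)/(1-r^2)}$ on $n-2-k$ df.  With no
  adjusters this is exactly the plain Pearson correlation, and it matches
  the partial correlation from the inverse correlation matrix to
  $10^{-10}$.
* **Effect modification** is tested by a likelihood-ratio comparison of
  nested Gaussian linear models with and without the exposure×modifier
  term: $\Lambda = n \log(\mathrm{RSS}_0/\mathrm{RSS}_1)$ on a $\chi^2$
  with one df per interaction column.  At $n = 800$ the empirical size at
  $\alpha = 0.05$ is within Monte-Carlo noise of nominal.
* **Forward stepwise selection** starts from the intercept (plus any
  forced terms) and repeatedly adds the candidate with the smallest
  partial-F p-value while that p-value is ≤ 0.05.  Entry and significance
  share the analysis-wide $P \le 0.05$; there is no removal step — both
  choices follow the stated "forward selection at $P \le 0.05$" rather
  than any software's default (e.g. SAS's 0.15).  Ties break by candidate
  order.  Every candidate's final status is reported: unselected
  candidates carry the p-value they would have had if added to the final
  model — the "dash" convention of stepwise regression tables.
* **The ancestry exposure** is selection-eligible like any candidate but
  always reported: its coefficient, SE, p-value and 95% CI come from
  refitting the selected covariate set plus the exposure.  This makes the
  exposure's interval well-defined in every stratum and every replicate,
  whether or not it was selected.
* **Stratified models** run within non-obese/obese and
  non-IR/IR strata (plus a diabetes-free sensitivity subset), with the
  stratifying variable removed from its own candidate list (BMI within
  obesity strata, HOMA-IR within IR strata).  Strata under 50 observations
  are skipped.  Interaction tests use the full candidate set rather than a
  stepwise-selected one; which set the original analysis used is not
  stated, so the choice is documented here.

Because covariates are selected before the exposure model is refit, the
exposure's 95% interval is mildly approximate (post-selection inference);
in repeated sampling at the default generator settings its coverage sits
a percent or two below nominal, which is why the recovery checks accept
coverage in a band around 95% rather than exactly at it.

## Spline linearity testing

`fit_pea_spline()` fits the Gaussian additive model
log-adiponectin ~ covariates + $f$(PEA) with a penalized cubic regression
spline (basis dimension $k = 10$, knots on quantiles, smoothing parameter
by GCV) and compares deviances against two nested models: the
covariates-only model (does ancestry carry signal at all?) and the model
with a linear ancestry term (does the smooth add anything beyond a
line?).  Both comparisons use mgcv's approximate F-test on reference
degrees of freedom; a raw-edf F-test proved anti-conservative in
calibration and is not used.  A relation is declared non-linear only
under the compound rule: *significant non-linearity and estimated degrees
of freedom greater than 3*.  Forcing the penalty to infinity collapses
the smooth onto the straight line (edf → 1, fitted values equal OLS),
and because knots sit on quantiles the fit is invariant to affine
rescaling of the exposure.

The decision-rule calibration simulations use a uniform exposure on
$[0, 1]$ so that the spline basis spans its whole range: under linear
truth the rule stays silent in well over 90% of replicates, under a
strong cubic signal it detects non-linearity essentially always.  The
borderline stratum-specific p-values of the original cohort depend on
that cohort's data and are not a simulation target; only the machinery
is.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without
any data download, and its defaults *are* the study conditions: 1439
individuals, 1447 AIMs at mean differential 0.4, true PEA drawn
Beta(4.671, 23.475) — quantile-matched (see `match_pea_beta()`) to median
0.158 and IQR 0.093; the implied mean ± SD of 0.166 ± 0.069 is consistent
with the descriptive 17.3 ± 8.1 (%) up to the distribution's skew —
62% women, age 48 ± 12 truncated at 21, sex-specific BMI (33.0 ± 7.4
women, 29.5 ± 5.7 men) putting roughly half the cohort over the obesity
threshold, 17% missing fasting insulin (249/1439), and log-normal
insulin, glucose, triglycerides and CRP.  A single latent adiposity
factor ties BMI, waist, insulin, HDL, blood pressure and CRP together —
a deliberately simple Gaussian-factor construction whose only purpose is
to reproduce the qualitative correlation structure (adiponectin
negatively related to HOMA-IR and adiposity, positively to HDL), not the
cohort's exact joint distribution.

The outcome is generated as

log(adiponectin) = 1.68 + slope·PEA − 0.28·male − 0.09·HOMA +
0.012·(HDL − 50) − 0.006·(waist − 99) + 0.002·(age − 48) −
0.012·(CRP − 5) + N(0, 0.5²),

which gives a marginal log-adiponectin spread close to the descriptive
4.7 ± 3.4 µg/mL and puts the stratified ancestry coefficient's standard
error near 0.28 at the non-obese stratum's size — the scale at which the
calibration targets live.

**Why one modifier at a time.** The calibration targets give the ancestry
slope as 0.62 among non-obese (0 among obese) and 0.74 among
insulin-sensitive (0 among resistant).  With ≈53% obese and 25% IR these
four numbers cannot all be marginal stratum slopes of a single outcome:
the strata cross, so an effect confined to the non-obese necessarily
leaks a diluted effect into both IR strata and vice versa.  The generator
therefore takes `pea_modifier = "obesity"` or `"ir"`, carrying the effect
modification through one classification per simulated cohort; recovery
checks run both arms, each against its own target.  True PEA and the
phenotype strata are otherwise independent, so interaction tests have
known truth.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real cohorts: linkage disequilibrium between AIMs
(the product likelihood's independence assumption is exact in simulation,
approximate in genomes), family structure, assay error in adiponectin,
genuinely skewed BMI, and any marginal distribution beyond the documented
calibration targets.

## Problem sizes and reproducibility

Every stochastic routine takes an explicit integer seed, and the pipeline
derives per-stage sub-seeds from one master seed; rerunning a
configuration reproduces every CSV byte for byte.  The validation suite
works at the study's own scale where the target is scale-dependent
(1439 × 1447 for ancestry recovery; 500 × 300 for cross-estimator
agreement; 100 individuals against a 10,000-point grid; 1000 replicates
at n = 800 for LRT size; 1000 replicates of six-candidate null selection;
200 replicates per arm for the spline rule; 500 replicates per modifier
arm for stratified recovery) and at reduced sizes for structural unit
tests.

## Known limitations

* Global two-way admixture only: no local ancestry, no three-way models,
  and no MCMC re-implementation of the reference admixture programs —
  the flat-prior posterior mean stands in as the agreement check.
* The likelihood ignores linkage between AIMs; with a genome-wide panel
  the point estimates are robust but the information-based SEs are
  slightly optimistic under LD.
* Stepwise selection is reported faithfully, but post-selection inference
  is approximate by construction; the exposure refit narrows, not
  removes, that gap.
* The IR quartile convention (pooled, average-rank) is one of several
  defensible readings of "upper quartile of the distribution"; it is
  deterministic and reproduces the 298/1190 split, but alternatives
  (sex-specific, post-exclusion) would shift the cut slightly.
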