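---
title: "Methods: meta polygenic scores and multistate life expectancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta polygenic scores and multistate life expectancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`prslife` implements two pieces of machinery that together turn cohort
follow-up data and genome-wide association results into a single,
communicable quantity: how many years of life, and of life free of
cardiovascular disease (CVD), separate people in different genetic-risk
and lifestyle groups. This vignette is the package's account of the
models it uses, the choices it makes where several defensible options
exist, and what its validation does and does not establish.

## The illness-death model and its three transitions

Follow-up is represented as an irreversible three-state process: from
CVD-free a person can develop CVD (transition 1) or die of a non-CVD
cause (transition 2); once CVD has occurred, the only further move is
death from any cause (transition 3). Only the first entry into a state
counts, and there is no recovery or backflow. Three quantities feed the
life table:

1. **Age-specific pooled rates.** `fit_rates()` fits a Poisson
   log-linear model of 1-year event counts on an age basis with a log
   person-time offset, pooling all exposure groups. The default basis is
   linear in age on the log scale — a Gompertz-type rate, which is both
   the standard demographic description of adult mortality and exactly
   the generative form of the package's simulator, so rate-model
   misspecification can be separated from other error sources in tests.
   An intercept-only basis and a natural-spline basis (`df` chosen by the
   caller) are available where the log-linear assumption is too rigid.
   Transition-3 rates are indexed by *current age* in the diseased
   state, not by time since onset, because the life table is Markov in
   age (see below).

2. **Five-year prevalence by state.** `compute_prevalence()` tabulates
   the person-time share of each exposure category within 5-year age
   bands (40-44 ... 85-89), separately for the CVD-free and CVD states.
   Empty cells inherit the nearest non-empty band in the same state,
   with a message; a state with no person-time at all falls back to the
   disease-free composition.

3. **Hazard ratios.** `fit_hrs()` estimates Cox models per transition
   (Efron ties). Transitions 1-2 use age as the time scale with left
   truncation at entry; transition 3 uses time since onset as the time
   scale with age at onset as a covariate, the convention that keeps the
   post-onset baseline interpretable while the life table itself stays
   on the age scale. As a collider-bias sensitivity analysis,
   `ipw_reweight()` supplies stabilized inverse-probability weights
   (marginal case fraction over fitted case probability, truncated at
   the 1st/99th percentiles) for a weighted transition-3 refit.

## From pooled rates to group-specific life tables

The pooled rate, the prevalence, and the hazard ratios are reconciled by
the calibration identity implemented in `calibrate_group_rates()`:

$$\lambda_{i,g}(x) \;=\; \lambda_i(x)\,
  \frac{HR_{i,g}}{\sum_h \pi_h(x, s_i)\, HR_{i,h}},$$

where $s_i$ is the at-risk state of transition $i$ (CVD-free for 1-2,
CVD for 3). The prevalence-weighted mean of the group rates reproduces
the pooled rate identically — the package tests this to $10^{-12}$ —
so the group tables are mutually consistent with the population table
by construction.

Within each 1-year interval the hazards are held constant and the
competing exits from the CVD-free state split exactly:

$$q_{f\to c} = \frac{\lambda_1}{\Lambda}\bigl(1 - e^{-\Lambda}\bigr),
\qquad
q_{f\to d} = \frac{\lambda_2}{\Lambda}\bigl(1 - e^{-\Lambda}\bigr),
\qquad \Lambda = \lambda_1 + \lambda_2,$$

with $q_{c\to d} = 1 - e^{-\lambda_3}$. This exponential split is exact
under the piecewise-constant model (no half-rate approximation), which
makes it directly checkable against a within-year integration.

`build_lifetable()` then runs the discrete recursion from a radix of 1
entirely in the CVD-free state at age 40:

- survivors leave CVD-free via the two competing probabilities;
- new entrants to the CVD state face half an interval of transition-3
  risk in their onset year (the standard mid-interval convention);
- person-years per interval are trapezoidal in the occupancies, so new
  entrants are credited about half a year in the diseased state;
- the table closes at 90 with no open-ended interval. All expectancies
  are therefore *temporary* life expectancies over 40-90, bounded by 50
  years; this matches populations whose follow-up does not support
  rates beyond 90.

`life_expectancy()` sums person-years: total LE, CVD-free LE, LE with
CVD (total minus free, exactly, by construction), and the CVD-free
proportion.

### Numerical behavior

The discrete 1-year engine is validated against
`true_life_expectancy()`, an independent continuous-time oracle that
integrates the Kolmogorov forward equations of the same illness-death
model with `deSolve` at tolerance $10^{-10}$. On the default generative
hazards the 1-year engine is within about 0.012 years of the oracle,
and `build_lifetable(step = h)` converges monotonically toward it as
the interval is refined ($h = 1, 0.5, 0.25$). Degenerate inputs are
handled by limits: zero hazards give zero probabilities, and a rate of
zero is representable as a $-\infty$ log-rate coefficient.

## Parametric bootstrap

`bootstrap_ci()` propagates input uncertainty by Monte Carlo, 10,000
runs by default. Per run it draws

- Poisson coefficient vectors from a Gaussian with the fitted
  covariance (Cholesky; degenerate covariances fall back to their
  diagonal with a warning; exactly-zero covariances draw no noise);
- log hazard-ratio vectors from a Gaussian with the Cox covariance of
  the group terms;
- each (band, state) prevalence row from a Dirichlet whose
  concentration is the observed proportions scaled by the cell's
  effective person-years, so cells with more exposure are drawn more
  tightly.

All groups are rebuilt from the *shared* draw within a run, so
`le_difference()` computes between-group contrasts within runs and its
percentile intervals reflect the contrast uncertainty rather than
twice the shared input uncertainty. Intervals are percentile 2.5/97.5.
These distributional choices are stated here and recorded in the result
metadata because the exact conventions used for published tables of
this kind typically live in supplements and cited prior work;
reproduced values may accordingly differ at the 0.1-year level.
In a 200-cohort simulation study (500-run bootstraps, two groups,
n = 6,000) the intervals cover the generative life expectancies at
94-97%, within the 90-99% band the package's acceptance suite demands.

## The meta polygenic score

`metaprs` builds a PRS for a composite outcome in three stages,
mirroring meta-scoring practice for heterogeneous endpoints:

1. **Candidates.** `clump_and_threshold()` greedily prunes GWAS
   variants in ascending p-value order, discarding any variant whose
   squared dosage correlation with an already-kept variant within the
   window reaches the threshold, then forms one candidate per p-value
   cutoff. The default grid (r² in 0.1/0.2/0.5, 250 kb, seven p
   cutoffs) spans standard practice and is fully configurable; the
   published grids behind large candidate counts are rarely stated
   exactly. Externally built weight files (e.g. lassosum or PRS-CS
   output) enter as `method = "external"` candidates through the same
   PGS-style TSV reader.
2. **Selection and ancestry integration.** `select_optimal_prs()` keeps
   the candidate with the largest absolute Wald z in a logistic model of
   the training outcome on the standardized score plus covariates (ties
   to the earlier candidate; separation flagged and skipped).
   `aic_integrate()` chooses between a European score, an East Asian
   score, or both, by AIC of the corresponding logistic models; nearly
   collinear pairs (|r| > 0.999) fall back to the better single model.
3. **Stacking.** `elasticnet_stack()` combines the trait scores by
   penalized logistic regression over a small mixing grid
   (alpha in 0.1/0.5/0.9) with a seeded ten-fold assignment. The mixing
   value is chosen by minimal cross-validated deviance; *within* the
   chosen mixing the penalty uses the one-standard-error rule by
   default. The 1-SE choice is deliberate: under a zero-signal outcome
   the deviance-minimizing penalty retains spurious small coefficients
   in a third to a half of replicates, while the 1-SE stack is empty
   essentially always, and with a genuinely informative trait at
   n = 5,000 both rules retain it (`lambda_choice = "min"` restores the
   strict minimizer). Stacking is covariate-free on standardized
   scores; covariates act in the selection stages and in the downstream
   Cox models instead, which keeps the stacked weights portable as a
   pure variant-weight expansion (`variant_expansion` reproduces the
   stacked score to correlation 1 on any panel).

Quintile categorization (`categorize_prs()`) is rank-based — category
k ends at rank ⌈kn/5⌉, ties broken by stable input order — so it is
exactly invariant to monotone transforms of the score and reproducible
without interpolation ambiguity.

## Lifestyle classification

`classify_lifestyle()` flags six factors (smoking including quitting
for illness; any of three diet habits; activity below the sex/age
stratum median; sleep outside 7-9 h; BMI outside 18.5-24; waist at or
above 90/85 cm for men/women) and counts them into favorable (0-1),
intermediate (2-4), unfavorable (5-6). Two readings were open: activity
*equal* to the stratum median is favorable by default (the "lower half"
read strictly), with `pa_at_median_unfavorable` to flip it; and former
smokers who quit for reasons other than illness are favorable. Missing
fields are rejected outright rather than imputed.

## The synthetic study population

`simulate_cohort()` generates the population the package is tested on:
entry ages uniform on 30-79, a 40% male fraction, 12 years of
administrative follow-up, Gompertz baseline hazards
$\lambda_i(x) = a_i e^{b_i x}$ with defaults
$a_1 = 1.25\times10^{-4}, b_1 = 0.085$;
$a_2 = 3.5\times10^{-5}, b_2 = 0.095$;
$a_3 = 2\times10^{-4}, b_3 = 0.09$, and multiplicative group hazard
ratios. The defaults were calibrated analytically, once, so that about
a quarter to a third of the cohort develops CVD over follow-up and the
incidence rate near the cohort's mean attained age is about 2%/year —
the regime of a large middle-aged cohort with a broad CVD endpoint.
The default three-group exposure (prevalence 20/60/20, transition HRs
1/1.20/1.63, 1/1.01/1.11, 1/1.07/1.25) mirrors a quintile-based
genetic-risk classification; lifestyle-like margins (15.5/77.6/6.9)
appear in the joint-exposure tests.

Latent event times come from the Gompertz inverse CDF; disease and
non-CVD death compete from entry, and post-onset survival is drawn from
the transition-3 hazard indexed by current age — i.e. the generative
process is Markov in age, matching the life-table engine's assumption
rather than probing it. Each individual consumes a dedicated RNG
sub-stream whose seed is drawn sequentially from the master stream, so
cohorts are nested in n (growing the cohort leaves earlier individuals
untouched) while cohorts with different master seeds are independent.
An earlier design derived sub-seeds as master + index, which silently
made cohorts with adjacent seeds near-copies of each other; the
sequential-draw design is the reason the package's coverage study is a
genuine replication study.

What the simulator deliberately does *not* emulate: regional or
clustered recruitment, loss to follow-up other than administrative
censoring, lifestyle drift over time, real linkage-disequilibrium
patterns (genotypes are independent binomial dosages;
`block_ld_panel`-style correlated panels are constructed in tests where
LD matters), or duration effects in post-onset mortality. Passing tests
therefore establish internal consistency of estimator and engine under
a correctly specified Markov model, not robustness to those realities.

`true_life_expectancy()` doubles as the ground truth for end-to-end
recovery: in 10 replicate cohorts of 20,000, fitted log HRs fall within
3 SE of truth and the generative life expectancies fall inside the
bootstrap intervals in at least 90% of checks.

## Problem sizes used by the test suite

Simulation sizes are the package's own trade-off between resolution and
turnaround: closed-form and survival-law checks run at n = 50,000
(binomial error small enough to detect 1% biases); end-to-end recovery
uses 10 replicates of n = 20,000 with 200-run bootstraps; the coverage
study uses 200 cohorts of n = 6,000 with 500-run bootstraps; stacking
checks use n = 5,000 with 14 traits. The full suite runs in a few
minutes on one CPU.

## File formats and the command line

Cohorts travel as CSV (`read_cohort()` validates age ordering row by
row and reports offending line numbers); GWAS summaries and PRS weights
as tab-separated text with mandatory headers; life-table inputs as
three CSV sheets (rate coefficients, prevalence, Cox coefficients) with
a remappable column layout via `read_lifetable_sheets()` — the same
three roles as the supplementary workbook that accompanies published
tables of this kind, so an exported workbook drops in directly. Missing
standard errors degrade to point-estimate-only mode with zero-width
intervals rather than failure. A thin command-line wrapper
(`inst/cli/prslife`) chains `simulate`, `fit-transitions`, and
`lifetable` for shell pipelines and writes a metadata JSON (package
version, seed, config hash) next to every output; the exported
functions remain the primary interface.

## Known limitations

- Life expectancies are 40-90 temporary expectancies; they understate
  full-lifetime differences whenever mortality beyond 90 differs by
  group.
- The engine is Markov in age: duration dependence of post-onset
  mortality is absorbed into the age-indexed transition-3 rate. The
  Cox transition-3 model (duration time scale, onset-age adjusted) is
  consistent with this only when the true hazard is close to
  proportional in both directions, as it is in the simulator.
- Prevalence enters as 5-year step functions; strong within-band
  composition gradients would bias the calibration slightly.
- The bootstrap treats the three inputs as independent; in reality the
  rates and HRs are estimated from the same cohort and correlate
  weakly.
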