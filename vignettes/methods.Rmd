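---
title: "Methods: psychometric model, bootstrap inference, and the synthetic observer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: psychometric model, bootstrap inference, and the synthetic observer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viscoweber)
```

## The problem

In a two-alternative forced-choice (2AFC) viscosity discrimination task an
observer judges, for each pair of fluids, which one is "thicker". With the
method of constant stimuli each reference fluid is paired with a fixed set
of test fluids bracketing it, and the frequency of "test thicker" responses
traces out a psychometric function of test viscosity. Two quantities of
scientific interest fall out of that curve:

* the **Weber fraction** `w` — the relative viscosity change needed for
  reliable discrimination, i.e. perceptual sensitivity;
* the **point of subjective equality (PSE)** `p` — the test viscosity
  perceived as equal to the reference, whose displacement from the true
  reference measures perceptual **bias** (here: driven by fluid appearance,
  opaque versus transparent).

## The model

Responses are pooled over participants per pair ("average participant")
and the k-of-n counts are fit with a cumulative-Gaussian (error-function)
curve in *log* viscosity, parameterized directly by the Weber fraction:

$$f(\eta) = \frac12 + \frac12\,
  \mathrm{erf}\!\left(\frac{\log(\eta/p)}{\sqrt2\,\log(w+1)}\right)$$

The parameterization is chosen so that the curve passes through 84.13%
(`pnorm(1)`) at `eta = p(1+w)` and 15.87% at `eta = p/(1+w)`; those two
points are the JND bounds. The log base cancels between numerator and
denominator (asserted to 1e-12 in the tests); the package uses the natural
log internally as a fixed convention.

Assumptions worth keeping in mind:

* **Independent binomial likelihood per pair.** The pooled counts are
  treated as independent binomials; there is no overdispersion term, so
  between-subject heterogeneity is absorbed into a flatter pooled curve
  (see "aggregation flattening" below).
* **No lapse term.** The fitted model has no stimulus-independent error
  rate; a lapse parameter exists only in the simulator, to probe
  robustness.

## Fitting

`fit_psychometric()` minimizes the clipped binomial negative
log-likelihood over `(log w, log p)` inside the box `w in [0.1, 100]`,
`p in [10, 20500]` cP, starting from `(0.5, p_true)`. Two modes mirror the
two experimental questions:

* `fixed_p` (discrimination tasks): `p` is pinned to the true reference —
  the design is symmetric, so any PSE displacement would be an artefact —
  and only `w` is estimated (1-D Brent optimization).
* `free_p` (bias tasks, where reference and test differ in appearance):
  both parameters are estimated (L-BFGS-B, with a penalized Nelder-Mead
  restart if the gradient method fails).

Numerical choices: probabilities are clipped at 1e-9 before taking logs so
that `k = 0` / `k = n` rows cannot produce infinite likelihoods; the
convergence tolerance is ~1e-8 on the NLL; an optimum within 1e-4 relative
log-distance of a box edge is reported at the bound with
`converged = FALSE` (never an exception) — degenerate tables (all `k = 0`
or all `k = n`) are handled the same way. The equal-viscosity catch pair
contributes no slope information in `fixed_p` mode (its model probability
is identically 0.5) but is informative in `free_p` mode, so it is always
included.

## Bootstrap inference

Uncertainty comes from a participant-resampling percentile bootstrap
(`bootstrap_fit()`): for every test-reference pair independently, the N
pooled responses are resampled with replacement (N = number of responses
for that pair) and the model refit, 5000 times by default. Percentiles of
the sorted draws give CIs (`percentile_interval()`, type-7 quantiles); the
draw mean is reported alongside.

* **Difference tests** (`difference_test()`): draw-by-draw differences of
  two independent bootstrap samples; the mean difference, its percentile
  CI, and two p-value flavours. The empirical two-sided sign fraction is
  floored at `1/(B+1)` and cannot resolve below that, so a normal
  approximation on the difference draws (`p_normal`) is reported side by
  side and used for the headline `significant` flag. Reported p-values far
  below the empirical floor are only meaningful under that approximation.
* **Bias tests** (`bias_test()`): the same machinery applied to the draws
  of `p - p_true` from a free-p fit. Positive values mean the transparent
  test must be physically thicker than the opaque reference to match.
* **Bonferroni correction**: family sizes are always supplied by the
  caller/config (five reference-wise bias comparisons, ten pairwise Weber
  comparisons at base alpha 0.05 in the canonical analysis); the package
  never infers a family size from the data.
* **Exclusion rule** (`exclude_poor_fit()`): a Weber fraction whose 95%
  CI is 2 units wide or more is reported as N/A — wide intervals are the
  operational signature of a near-flat, unidentifiable curve.

RNG discipline: one root seed; per-iteration substreams are pre-drawn
sequentially, so extending the iteration count leaves earlier draws
unchanged, and the entire pipeline output is a pure function of
(trials, config, seed).

A conflict resolved during development: refits of *step-function*
resamples (every participant identical per pair) necessarily pin `w` at a
bound and are flagged non-converged; `bootstrap_fit()` therefore errors
only when no refit yields a usable estimate at all, warns when more than
20% are flagged, and otherwise keeps all draws — this preserves the
degenerate-data contract (identical draws, zero-width CI) while still
surfacing wholesale failure.

## Per-subject robustness checks

Because aggregation could manufacture a population-level bias from a
skewed minority, the package also works at the per-subject level:
`per_subject_percentages()` tabulates each participant's percentage of
"test thicker" responses per group, `screen_participants()` flags (never
deletes) stereotyped responders (always test / always reference / always
left / always right), and two rank tests compare the percentage tables:

* `mann_whitney_u()` between cohorts, reporting the U of the first sample
  *and* its complement `n1*n2 - U` (the literature uses both conventions);
  midrank ties, tie-corrected normal p with continuity correction.
* `wilcoxon_signed_rank()` against the 50% baseline of an unbiased 2AFC
  population, with the drop-zeros convention and the smaller rank sum as
  the statistic.

Exact enumeration is used as the *test oracle* (all relabelings up to
8 x 8; all 2^n sign assignments up to n = 15); the package's reported
p-values are the normal approximations, which the suite shows agree with
enumeration to within 0.02 at those sizes. The factorial ANOVA sometimes
run on the same table is out of scope; the percentage table is emitted in
a layout any standard ANOVA routine consumes.

## The synthetic observer

`simulate_experiment()` generates trial-level data with the structure the
analysis assumes, so every stage is testable without the deposited study
data:

* **Design**: the five-group constant-stimuli layout, including the
  equal-viscosity catch pair per group (the arithmetic that reproduces the
  printed per-task pair counts, 32 same-appearance / 35 mixed) and the
  shared boundary pairs between adjacent same-appearance groups.
* **Sensitivity**: one Weber fraction per group (scenario presets echo the
  fitted study values, ~0.5-1.5).
* **Bias**: a multiplicative perceived-viscosity gain per appearance —
  the simplest mechanism consistent with a log-viscosity model and with
  viscosity-proportional PSE shifts. The mixed-task presets use a
  transparent gain of 0.38, anchored on the reported low-viscosity match
  (an opaque ~544 cP reference matching a transparent test near 1440 cP).
  An additive-offset variant sits behind `bias_model = "additive"` for
  sensitivity analysis.
* **Lapse**: symmetric `lambda/2 + (1 - lambda) f` contamination, default
  0 to match the analysis model.
* **Heterogeneity**: per-subject log-normal perturbations of `w`
  (`subject_sd_logw`) and of the appearance gains (`subject_sd_logbeta`),
  default 0. The study does not characterize subject variability, so
  non-zero values are package choices for robustness experiments, not
  empirical claims.

What a green test does and does not establish: the simulator draws
independent Bernoulli responses from the model itself, so recovery and
coverage tests validate the *inference machinery*, not the model's
adequacy for human data. Real responses are correlated within participant
across pairs (the bootstrap resamples per-pair responses, exactly like the
canonical analysis, and therefore ignores that correlation), may include
lapses, and need not follow an erf curve in log viscosity.

Two findings from building the simulator, documented because they differ
from first intuition:

* Scatter in `w` alone does not flatten the pooled curve — the pooled
  central slope averages `1/log(1+w)` across subjects, which by convexity
  *steepens* slightly. What flattens the pooled curve is between-subject
  scatter in the *match point* (here: gain scatter expressed in
  mixed-appearance tasks, fitted pooled w 0.60 to ~1.07 at
  `subject_sd_logbeta = 0.4`). The aggregation-flattening caveat is thus
  reproducible, but only through the PSE-scatter channel.
* With the global transparent gain 0.38, the highest-viscosity group's
  implied true PSE (reference/0.38 ~ 44,000 cP) lies *above* the `p`
  ceiling of the canonical fitting box, so its free-p refits pin at the
  bound and are flagged — the simulator faithfully reproduces the regime
  in which the original analysis had to exclude extreme groups, and the
  pipeline surfaces it through convergence flags and the N/A exclusion
  rule rather than hiding it.

## Scenario presets

| scenario | modality | appearance (ref/test) | pairs | N | mode |
|----------|----------|----------------------|-------|----|------|
| task1a | visual | T/T | 32 | 57 | fixed_p |
| task1b | visual | O/O | 32 | 57 | fixed_p |
| task1c | visual | O/T | 35 | 110 | free_p |
| task2  | haptic | T/T | 32 | 64 | fixed_p |
| task3a | visuo-haptic | T/T | 32 | 50 | fixed_p |
| task3b | visuo-haptic | O/T | 35 | 50 | free_p |

The printed trial count for the mixed visuo-haptic PSE task is 32 in the
source material, which conflicts with the no-overlap arithmetic that gives
35 for the visual mixed task; the preset uses the 35-pair design, and when
real trial files are analysed the design is always inferred from the file,
never forced. The opaque visual preset assigns group E a large Weber
fraction (2.5) so that the unfittable-group regime, and with it the N/A
rendering, is part of the stated world.

## Known limitations

* No overdispersion or hierarchical subject model; pooled fits inherit
  aggregation flattening by design.
* The percentile bootstrap is the plain variant (no BCa/studentized
  correction); its coverage at task scale is verified empirically
  (93-97% band) rather than guaranteed.
* Normal-approximation p-values below the empirical bootstrap resolution
  extrapolate beyond what 5000 resamples can certify.
* The simulator's bias is a single gain per appearance; the real
  viscosity-dependence of the bias (strong at low, absent-to-reversed at
  high viscosity) is not modelled.
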