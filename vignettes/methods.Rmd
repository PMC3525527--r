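---
title: "Methods: survey-based infertility estimation with a hierarchical space-time-age model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survey-based infertility estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the package's methodological choices: the
classification algorithm and its boundary conventions, the bias
correction, the hierarchical model and its priors, the sampler, what the
synthetic-data generator does and does not emulate, and the numerical
decisions that a maintainer would otherwise have to reverse-engineer.

## 1. Indicator definitions and boundary conventions

Four indicators are computed per survey and five-year age group
(20--24 through 40--44; ages 15--19 and 45--49 never enter
observations, as child-seeking behaviour at the extremes of the
reproductive period makes prevalence there unstable).

**Primary infertility.** Numerator: women in a union for at least five
years, with no live birth, desiring a child, and no contraceptive use
during the five-year exposure window. Denominator: the numerator plus
*fertile unions* — women with at least one live birth and at least five
years in union. Note the denominator's fertile arm carries no desire or
contraception condition: demonstrated fertility is enough.

**Secondary infertility.** Numerator: parous women in a union, desiring
another child, with at least five contraception-free union years since
the *last* live birth. Fertile arm: a live birth within the past five
years and at least five union years following the *first* birth. The
asymmetry (infertile clock on the last birth, fertile clock on the
first) is deliberate and implemented as stated; a consequence is that a
secondary-fertile union necessarily has two or more births. "Within the
past five years" is implemented as `years_since_last_birth < 5`, and
every "at least five years" as `>= 5`, on integer years.

**Exposure.** Exposure to primary risk: in a union and either (not
currently contracepting and desiring a child) or parous. Exposure to
secondary risk: in a union and either (parous, not currently
contracepting, desiring another child) or (a second or later child born
within the past five years). Exposure is a *current-status* quantity,
so only current contraceptive use enters it — there is no biased/
unbiased variant.

**Desire mapping.** Women undecided about having a(nother) child and
women declaring themselves unable to conceive are counted as desiring
one: both groups are unlikely to be preventing births in unobserved
ways, and excluding self-declared-unable women would selectively remove
the infertile.

**Missingness.** A record missing a field *on its decision path* is
excluded with reason `missing_data`; fields not needed for the record's
branch are not required (a woman out of union needs nothing else). No
imputation is attempted. A survey is dropped for an indicator when the
`missing_data` share among respondents aged 20--44 strictly exceeds
15% ("more than 15%" read literally, so exactly 15% stays in).

**Fallback measurement.** When five-year contraceptive history is
absent, current use stands in; when current-union duration is absent,
time since first union stands in. Either fallback marks the
observation `is_biased`. Ever-married-only samples contribute exposure
observations only at ages 30+, where essentially all women in the
relevant populations have been in a union. Countries carrying the
`china_rule` flag yield no secondary-infertility observations and are
excluded from secondary aggregates; the flag is applied to the
prevalence indicator at screening, since the exposure indicator is not
interpretable as infertility and the secondary aggregate excludes those
cells regardless.

**Effective sample size.** `effective_n` = classified denominator /
design effect. The design effect is survey metadata (1.0 simple random,
conventionally ~1.5 for clustered national surveys); the package does
not estimate it from the microdata.

**Weights.** The indicator ratio is unweighted by default; a weighted
option exists (`weighted = TRUE` uses the survey weights in the ratio,
keeping raw counts for the variance). The surveys' true weighting
schemes are not reconstructible from the available description.

## 2. Bias correction

Training pairs come from full-information surveys classified twice: with
the full history and with the fallbacks forced. The model is ordinary
least squares of `ln(unbiased)` on the biased estimate (proportion
scale), the age-group midpoint, and — secondary infertility only — the
prevalence of contraceptive use in the age group. One pooled regression
per indicator with age as a covariate (rather than one per age group)
was chosen as the smallest faithful reading; a per-group variant can be
obtained by filtering the pairs. Zero unbiased prevalences are
continuity-corrected by half a count before the log. Applying the model
replaces a biased observation's value with the exponentiated prediction
(clipped below 1 with a warning if needed) and attaches the prediction
variance — coefficient covariance term plus residual variance, mapped
from the log to the logit scale by the delta method
(`var_logit = var_log / (1-p)^2`). Unbiased rows pass through
unchanged, so total variance never decreases under correction.

## 3. From observations to model inputs

Analysis scale: logit. The transform is the *empirical logit*
`log((x + 0.5) / (D - x + 0.5))` — equivalently, the half-count
continuity correction applied to every observation, not only zeros —
because the plain logit of a binomial proportion with the small
infertile counts of low-prevalence cells is biased downward by Jensen's
inequality; the empirical logit removes the bias to second order and
reduces to the plain logit for large cells.

The sampling variance is the delta formula `deff / ((D+1) p (1-p))`,
evaluated **at the pooled proportion of the observation's
(indicator, age-group) stratum**, not at the observation's own value.
With counts of a few units, a variance of the form `1/(x + 0.5)` makes
precision weights correlate with the realized count, which biases every
precision-weighted summary upward (observed at about +0.4 standard
errors in simulation); evaluating the variance at the pooled proportion
removes the correlation while preserving the scale of the counts. The
bias-correction variance, already on the logit scale, is added to give
the observation's total known variance.

## 4. The hierarchical model

For one indicator, observation *i* from country *c*, year *t*, age
group *a*:

* `y_i ~ Normal(mu_i, v_i + sigma^2_nat)` (national) or
  `v_i + sigma^2_sub` (subnational),
* `mu_i = alpha_0 + u_r + u_s + u_c + (beta_0 + b_r) t_i + gamma x_i +
  delta_a + [delta_a^HI]`,

with `t` in decades centered at 2000, `x` the country-year mean years
of schooling centered at 7, age offsets `delta_a` with the 20--24 group
as reference, and an extra set of age offsets for exposure-to-primary
in the High-Income region (reference group again zero, so the HI level
itself is carried by the region intercept). Intercept deviations are
nested — `u_c ~ N(0, tau_c^2)` within subregion, `u_s ~ N(0, tau_s^2)`
within region, `u_r ~ N(0, tau_r^2)` around the global level — and
region slopes `b_r ~ N(0, tau_b^2)` around the global slope. Each of the
four indicators is fitted independently.

**Priors.** Fixed effects `N(0, 2^2)` on the logit scale (weakly
informative: prevalences from 0.002 to 0.98 within two standard
deviations of a 2% intercept). Half-Normal(1) on the hierarchical and
slope standard deviations. Half-Normal(0.5) on the national extra
standard deviation and Half-Normal(1) on the subnational one — the
asymmetry implements "subnational sources are less informative" while
letting the data decide the magnitudes. All scales are configurable in
`model_spec()`.

**Sampler.** Given the six standard deviations the model is
linear-Gaussian, so all location parameters are drawn *jointly* from
their exact multivariate-normal full conditional by Cholesky
factorization. Standard deviations are updated by slice sampling on the
log scale, followed by an ancillarity--sufficiency interweaving move
(holding `effects/sd` fixed, the sd's conditional is a truncated
normal): without the interweaving step the centered parameterization
mixes the variance components poorly (split-Rhat ~ 1.17 on
`tau_country` in the reference experiment; ~ 1.02 with it). Default: 4
chains, 500 warmup iterations, 1,600 retained draws total. Convergence
is declared at split potential-scale-reduction < 1.05 on every scalar
parameter; failure triggers a warning and a `converged = FALSE` flag
with the full diagnostics table — never silent output.

**Identifiability notes.** The decomposition of a country's level into
`alpha_0 + u_r + u_s + u_c` is resolved only by the priors; inference
should always use the composed linear predictor (`predict_prevalence`),
which is what the data pin down. With a single observation per country,
the country effect and the extra observation noise are confounded;
repeated observations (several age groups or years) separate them. Both
facts shaped the structural tests, which compare composed predictions,
not individual coefficients.

**Prediction.** Posterior prevalence draws are stored for every
(country, 1990--2010, age group) cell, including countries with no
data, whose draws integrate over the country-level prior — this is the
mechanism by which data-poor countries inherit subregional information
with honestly wider intervals. Observations may predate 1990 (their
year enters the trend term as-is; the education covariate is clamped to
its table range), but predictions are restricted to the 1990--2010
window.

## 5. Aggregation and reporting

All-women percent = prevalence x exposure, multiplied draw by draw.
Aggregates are population-weighted means over (country, age) cells
computed *within* each draw; "age-standardized prevalence among women
20--44" is exactly this population weighting — no external standard
population is introduced. Summaries are the draw mean and the 2.5/97.5
percentiles with linear interpolation between order statistics (R's
type-7 default; the convention is declared because the source does not
specify one). Trends subtract the 1990 draw from the 2010 draw;
`pp_increase` counts strictly positive differences (ties count as
non-increase — conservative, and only relevant for degenerate draws);
significance at pp > 0.975. Couples affected multiply all-women
proportions by the female population 20--44 per cell and sum; the
all-women (rather than in-union) denominator is a declared choice where
the source names the population data without a formula. Secondary
aggregates exclude `china_rule` cells.

## 6. The synthetic world

The generator exists so that every stage is testable against known
truth. A true surface is built on the logit scale with exactly the
model's structure (nested effects, linear decade trends, education
covariate, fixed age offsets, HI-specific exposure pattern), so
model-recovery experiments are *correctly specified* by construction —
a green coverage test establishes internal calibration, not robustness
to misspecification.

Survey records are drawn from a role mixture per age group whose masses
are solved so that full-history classification recovers all four true
values exactly in expectation. Two bias structures are planted with
masses *proportional to the true infertile mass* and declining with age
(multiplicative bias, worst for young couples): recent contraception
quitters (excluded under full history, infertile-looking under current
status) and remarried women whose first union predates a short current
union (infertile-looking under the first-union clock). Default
magnitudes 0.5/0.5/0.3 of the true infertile mass at the reference age
weight; at those defaults the biased estimator overstates primary
infertility roughly twofold at young ages.

Structural constraints worth knowing: by definition every
secondary-denominator woman is exposed to secondary risk, so
exposure-to-secondary can never fall below the secondary-denominator
share (about `prev_denominator_share x exposure-to-primary`); the
default surface keeps a margin above this floor, and the generator
clamps with a warning if a parameter choice violates it. Default sample
conditions: simple random samples (design effect 1.0, weights 1.0), 8%
of respondents outside the 20--44 window, education rising linearly
from country bases of 4--10 years, populations growing 1%/year from
bases of 50--500 thousand women per age group. The clustered-design
option only *declares* a design effect (inflating claimed variances);
records are always drawn independently — a stand-in, not a
reconstruction of real multistage sampling. Real-data features the
generator does not emulate: reporting heaping on durations, non-random
missingness, within-country heterogeneity, migration, and actual
cluster correlation.

## 7. Cross-validation

`run_cv` refits each indicator with all data from a random 20% of
data-bearing countries withheld, five times with independent samples
(the literal "five times, 20% each" reading; a rotating-partition mode
is not provided). Withheld observations are compared to the refitted
model's *posterior-predictive* intervals — cell prevalence draws plus
observation noise (known variance + fitted extra component) — since an
interval for the latent prevalence alone would be uncoverable by noisy
observations. Metrics: RMSE on the percentage-point scale, median
relative error `(pred - obs)/obs` (the signed convention is declared;
the source does not specify), and 95%-interval coverage. Fold
membership is seeded and logged, and the suite verifies metrics against
a brute-force recomputation from the per-fold detail.

## 8. Known limitations

* The sampler exploits the linear-Gaussian structure; replacing the
  normal likelihood (e.g. by a binomial) would require a different
  sampler for the location block.
* One correction model serves both missing-history patterns jointly;
  surveys missing only one of the two fields are corrected by a model
  trained on the joint degradation.
* The acceptance experiments run at desk scale (18 countries, 3 surveys
  each, 3,000 women per survey; CV with 2 chains and 800 draws) —
  deliberately smaller than a production fit, with thresholds chosen
  for that stated scale.
* Real-data headline quantities (global prevalence levels, CV errors of
  the original study) are not reproducible without the restricted
  survey microdata; the package's tests therefore check arithmetic
  consistency of printed numbers and statistical correctness on the
  synthetic world, nothing more.
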