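---
title: "Decomposing selection and evolution in a wild pedigreed population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing selection and evolution in a wild pedigreed population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Phenotypic selection estimates in wild populations routinely predict
evolution that never seems to happen. The covariance between a trait and
relative fitness — the selection differential — mixes two very different
things: a causal association between *genes* for the trait and fitness, and
an environmental association in which the same conditions (food, parasites,
territory quality) make individuals both, say, heavy and fecund. Only the
first drives evolution. `qgwild` implements the quantitative-genetic
machinery that separates the two in long-term individual-based studies of
pedigreed populations — the setting typified by an alpine snow vole
(*Chionomys nivalis*) monitoring study: roughly a thousand individuals over
nine annual cohorts, repeated body-mass/size measurements at trapping
sessions inside a snow-free season, lifetime and annual reproductive
success derived from a genetic pedigree, and overwinter survival records.

Every stage of the package can be validated by parameter recovery because
the package ships a generator (`simulate_study()`) that produces complete
study-shaped datasets from a declared truth.

# The models

## Additive relationship matrix

`validate_pedigree()` topologically sorts and checks the parent map;
`additive_relationship()` builds **A** by the tabular method (founders
`A_ii = 1`; offspring row = half the parents' rows; diagonal
`1 + F`), and `a_inverse()` constructs the sparse inverse directly by
Henderson's rules with the inbreeding correction. Unknown parents are
unrelated base-population founders; there are no genetic groups. Sorting is
Kahn's algorithm with ties broken by cohort then identifier, so matrix
construction is deterministic.

## The animal model

`fit_animal_model()` is a Gibbs sampler for Gaussian mixed models

y = Xb + Z_a a + Z_m m + Z_p p + Z_y y + e,

with `a ~ N(0, A ⊗ G)` and independent maternal, permanent-environment,
year and residual (co)variances, for one trait or several. Fixed effects
for morphological traits default to the standard capture correction: age
class, sex, their interaction, scaled Julian date and its square with age
and sex interactions, and the pedigree inbreeding coefficient as a
covariate (dropping it can bias the additive variance; keeping it is
harmless). Date-scaling constants are estimated once and stored with the
fit so any downstream prediction reuses identical scaling.

Relative fitness enters as a trait. Lifetime reproductive success is
standardized by sex-by-cohort means (`relativize_fitness()`), giving each
cell mean 1; fitness is then modelled as Gaussian *deliberately*, so that
its covariances with traits are directly interpretable as selection
differentials. Because fitness is measured once per individual, its
residual variance is fixed essentially to zero (`1e-8` times its observed
variance — exactly zero would break the conditional updates) and the
permanent-environment term carries its nonadditive variance. Internally,
fitness records live on their own rows with zero residual covariance to
the capture rows, so the likelihood factorizes and the near-zero variance
never enters an imputation step.

Priors are per-term inverse-Wisharts; the default scale splits the
observed phenotypic variance evenly across terms with a small degree of
belief (`k - 1 + 0.002`). Location effects are updated in blocks — fixed
effects per trait, breeding value and permanent environment *jointly* per
individual (they share the same records and mix poorly when updated
separately), maternal effects per mother, year effects per year — and each
covariance from its conditional inverse-Wishart. The sampler is written in
compiled code; a 60,000-iteration chain on a four-trait model with ~900
individuals takes a few minutes.

Point estimates are posterior modes of a Gaussian-kernel density
(`posterior_mode()`, Silverman bandwidth) and intervals are 95% highest
posterior density intervals, with `p_mcmc()` as the posterior tail
probability.

The heritability denominator sums all fitted random components plus the
residual; whether the among-year variance belongs in "phenotypic variance"
is genuinely debatable (it is variance among seasons, not among
individuals within a season), so `heritability(..., exclude_year = TRUE)`
reports the alternative.

## Selection decomposition and predicted responses

Per posterior sample, the selection differential on trait *z* is the sum
of the trait-fitness covariances at the additive, maternal,
permanent-environment and residual levels; the among-year covariance is
excluded because covariation between years is not selection among
individuals (and cohort standardization makes it effectively zero anyway).
The decomposition `sigma_P = sigma_A + sigma_E` holds exactly, sample by
sample, because it is computed that way — the additive part *is* the
Robertson–Price genetic differential `sigma_A(z, w)`, the predicted (used
retrospectively: realized) rate of genetic change per generation.

Gradients are `beta = (G' + P' + R')^{-1} S` with the fitness row/column
dropped from each matrix. The maternal covariance is excluded from the
phenotypic denominator in the estimator's standard form; because one can
argue either way, `include_maternal = TRUE` adds it and both can be
reported. `predict_response()` returns, per posterior sample, the
univariate breeder's equation `h^2 S`, the multivariate form `G' beta`,
the constrained form `(G' * I) beta` (off-diagonals zeroed, isolating the
effect of genetic correlations), and the Robertson–Price differential —
per generation and per year, dividing by the mean parental age
(`generation_time()`) sample-wise so the two scales are exactly
proportional.

Fitness components (`decompose_by_component()`): annual reproductive
success and overwinter survival are relativized within sex-by-year cells,
averaged per individual, and refitted as bivariate trait-component models
on the appropriate subset (adult males, adult females, adults, juveniles).
Averaging per individual is a deliberate simplification: a repeated annual
record with a pinned zero residual would be internally inconsistent, and
the individual mean preserves the covariance interpretation. Survival out
of the final monitored year is right-censored and excluded. Statistical
support is reported as posterior tail probabilities; generalized linear
model significance machinery is intentionally out of scope.

## Realized genetic change and the drift null

`blup_trend()` regresses cohort means of the breeding-value samples on
cohort year *within each posterior sample*, so the slope's posterior
carries both the non-independence of the predictions and their sampling
variance — summarizing first and regressing once would understate the
uncertainty and bias the trend toward the phenotypic one.

`gene_drop_drift()` asks whether such a trend could be drift alone: for
each posterior draw of the additive variance it simulates neutral breeding
values down the *observed* pedigree (founders `N(0, V_A)`; offspring =
midparent + Mendelian sampling `N(0, V_A (1 - (F_s + F_d)/2)/2)`) and
recomputes the same cohort slope. The drift replicate is paired with the
posterior draw that generated it — large `V_A` implies both a larger
estimated change and a larger drift variance, so an unpaired comparison
would be anticonservative. The default tail is one-sided in the observed
direction; a two-sided option exists because both conventions are
defensible.

`to_darwins()` converts a per-year rate to Darwins as
`|ln((mean + rate)/mean)| * 1e6` and returns the formula with the number,
since conventions differ in which mean and interval are used.

## Juvenile growth and viability selection

`fit_growth_survival()` jointly models juvenile capture histories and
overwinter survival. Masses follow a monomolecular curve
`m(t) = a_i (1 - exp(-k_i (t - t0)))` from the litter's conception-scale
birth date `t0` ("birth date" throughout means the projected time of zero
mass, i.e. conception), with measurement-error SD fixed at 2.05 g — the
value observable from animals weighed repeatedly on the same day.
Juveniles of one mother-year are clustered into at most 5 litters at least
20 days apart (natural-history constants); litters are latent, with
discrete Gibbs assignment and Metropolis date moves inside the
order/spacing constraints, so litter count is inferred up to the cap.
Individuals within a litter share `t0`; per-individual offsets are not
modelled and this is the identifying assumption for the litter structure.
Labels are identified by date ordering. `(a_i, log k_i)` are exchangeable
bivariate-normal draws whose mean and covariance get conjugate updates;
the implied correlation between asymptotic mass and growth rate is a
reported quantity. Survival is Bernoulli on the logit scale in sex,
predicted adult mass `a_i`, days from `t0` to the first snowfall, and the
mass-by-days interaction — the interaction is the scientifically central
parameter: it makes viability selection on adult mass depend on how much
growing season a litter has left.

**Identifiability.** With one to three captures per juvenile, the
per-litter curvature information (~2 g across a typical capture span) is
comparable to the measurement error, so `(t0, k, a)` forms a ridge: flat
curves with earlier conception dates and inflated asymptotes fit almost as
well and are favoured by sheer posterior volume. We verified this is a
property of the posterior, not the sampler, by initializing chains at the
generating truth of a synthetic study: they migrate to the drifted basin.
Three pieces of external information restore identification, and all are
defensible study facts rather than tuning: (i) the asymptote prior is
anchored at the near-asymptotic masses actually observed (default: the
97.5% mass quantile, variance 9 g²) — equivalently the adult mass of the
population; (ii) the growth-rate prior carries the timescale (default
`log k ~ N(log 0.02, 0.2^2)` per day, i.e. 90% of asymptotic mass ~115
days after conception), in the same spirit as the externally fixed
measurement SD; (iii) a detection-window constraint (a steep soft
penalty): with per-session capture probability near one, a juvenile's
first capture happens at the first session after it becomes trappable, so
its conception-to-first-capture age cannot exceed the emergence allowance
(default 30 days) plus that year's widest between-session gap — a bound
derived per year from the observed capture schedule itself
(`max_first_capture_age` overrides it with a global scalar). The bound
must dominate the design's true offset support: a tighter constant
truncates genuinely late-discovered litters, a much looser one reopens
the ridge. All three are arguments; sensitivity analyses simply refit
with different values. The sampler additionally uses compensated moves (litter-date
shifts with growth rates adjusted to preserve each juvenile's fitted mass
at its mean capture day, and a per-juvenile reparameterized walk along the
`(a, k)` ridge) so that the posterior honestly spans what the data cannot
pin.

Downstream summaries: `selection_on_adult_mass()` gives year-group
logit-scale gradients `gamma_mass + gamma_interaction x days` integrated
over the group's posterior birth-date distribution, plus survival-vs-mass
curves; `phenology_regression()` regresses each year's earliest posterior
birth date on snowmelt date (mean onset lag with SE; with no snowmelt
variation the slope is undefined and the function falls back to the mean
lag with a warning); `population_survival_shift()` integrates the fitted
survival curve over the observed covariate distribution under a shift of
predicted adult mass; `posterior_predictive_check()` reports tail
probabilities for a mass discrepancy (standardized squared residuals) and
a survival deviance.

Survival covariates are centred internally for sampler geometry only; all
reported coefficients are on raw scales (grams, days).

# The synthetic world

`sim_config()` declares the generating truth; its defaults *are* the
package's reference study conditions and mirror the published point
estimates of the snow-vole system wherever one exists: additive variance
4.34 g² for mass and 0.10 for relative fitness (heritabilities ~0.21 and
~0.06 against the default variance partition), genetic mass-fitness
covariance −0.35 g (per-year Robertson–Price rate −0.29 g/y at generation
time 1.2 y), permanent-environment mass-fitness covariance +1.21 g so the
phenotypic selection differential is +0.86 g, genetic correlations 0.79 /
0.40 / 0.56 among mass, body length and tail length, mean adult mass
41.7 g (SD 5.2), measurement error SD 2.05 g, conception onset 40 days
after snowmelt, survival interaction +0.0025 per gram per day, and a
season structure of two long snow-free years followed by short ones.
Where the source system reports no number the defaults are realistic
rodent-demography choices, stated once: litter size `1 + Poisson(2.8)`,
litters per dam-year `1 + Poisson(0.2)` capped at 5, adult annual survival
0.22 and juvenile overwinter survival ~0.35-0.4 (high-turnover demography
is what makes the generation time ~1.2 y), a ceiling of 28 breeding
females as crude density regulation, 5 trapping sessions per season, and a
0.03 probability of same-year female breeding. The survival logit
intercept and day coefficients are chosen so that the selection gradient
on predicted adult mass is ~−0.002/g when ~85 days of season remain and
~−0.10/g when ~45 remain, and juvenile survival is roughly flat in birth
date at the mean mass — the published selection geometry.

A juvenile's asymptotic ("predicted adult") mass inherits its mass
breeding value, with an independent environmental remainder keeping the
total SD at 5.2 g and carrying the weak negative correlation with growth
rate — so genetic change in mass appears as a cohort-level decline in
predicted adult mass, as in the source system.

Two things make the generated pedigree carry *real* selection rather than
merely labelled fitness: reproductive allocation (sire sampling and extra
litters) is weighted by the latent Gaussian fitness trait, and juvenile
overwinter survival depends on the mass latent (breeding value +
permanent environment) at a configurable logit slope (default −0.08/g for
juveniles, 0 for adults). The latent fitness trait (`omega`, mean 1)
carries the configured genetic and permanent-environment covariances and
is what the animal model fits; realized lifetime reproductive success is
bookkept from the pedigree separately, so the Robertson–Price identity can
be checked against actual transmission.

The generator is deterministic given the seed, with named substreams per
stage so adding a stage never perturbs another. What it does *not*
emulate: capture failure (detection is 1 given presence, as effectively in
the source system), immigration, spatial structure, genotype data, and
within-season juvenile mortality before first capture — so recovery tests
validate the estimators under these idealizations, not under every
real-data pathology.

# Numerical choices

* Fitness residual pinned at `1e-8` of its observed variance; its residual
  covariances are exactly zero (required for positive-definiteness).
* Singular gradient denominators or non-positive variance draws are
  skipped and counted, never imputed.
* All matrix draws go through Cholesky factorizations with tiny jitter
  (`1e-10`-`1e-12`) only where a configured covariance may be exactly
  singular.
* Zero-variance traits in the generator produce exactly zero deviations.
* The drift null's replicate count defaults to one per posterior draw
  (1000 total).
* Chain presets: tests and desk analyses use scaled-down chains (the
  package default `mcmc_settings()`: 60k/10k/50; growth: 20k/5k/15 x 3
  chains); `mcmc_long()` and `growth_mcmc_long()` reproduce
  publication-scale settings (1.3M/300k/1000 and 6.3M/300k/6000). The
  test-suite problem sizes are ~300-900 individuals, 20 replicates for
  the variance-recovery coverage check, 3 replicates for the
  breeder's-equation band-overlap check, one ~600-juvenile replicate for
  growth recovery, and 20 truth-level replicates for the sign-pattern
  check; these sizes are the package's chosen desk scale.

# Known limitations

* The Gibbs sampler has no parameter-expansion option; variance components
  very close to zero mix slowly and need longer chains.
* Fitness is Gaussian by design; there is no generalized-linear-model
  family support, and significance comes from posterior summaries only.
* The growth model's absolute timescale is prior-identified (see above);
  with sparser capture schedules than ~2 captures/juvenile the asymptote
  scale is a prior statement, and honest use requires the sensitivity
  arguments.
* Fitness components use per-individual mean relative measures, not
  repeated annual records.
* The juvenile/adult mass split model treats the two as separate traits
  measured on disjoint rows; their residual covariance is only weakly
  identified (through imputation) and the genetic correlation is the
  quantity to interpret.
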