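---
title: "Mapping stage-specific cancer incidence over small areas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping stage-specific cancer incidence over small areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Why map incidence by stage

Progress in early cancer detection is often monitored through the
*proportion* of cases diagnosed late. That statistic is treacherous: if
screening inflates the number of early-stage diagnoses while the late-stage
rate stays unchanged, the late-stage proportion falls although nothing about
harmful disease has improved; and because early-stage detection is strongly
patterned by affluence, proportions computed among cases inherit a
compositional gradient that looks like — but is not — an excess of dangerous
tumours in deprived areas. `stagemap` implements the alternative: model the
*incidence* of each stage separately over small areas, smooth it properly,
and read inequalities off the stage-specific incidence surfaces.

The package covers the full chain for a melanoma-style application: stage
recoding from tumour measurements (Breslow thickness, ulceration,
nodal/distant spread), direct age-standardisation for time trends, indirect
standardisation for small-area expected counts, Besag–York–Mollié (BYM)
spatial smoothing by MCMC, posterior-probability signal classification,
deprivation-quintile regression, a case-level late-stage logistic model, and
a purely spatial scan statistic as a sensitivity check. A synthetic-data
generator stands in for confidential registry inputs.

## The smoothing model

For one stage, area $i$ contributes an observed count $O_i$ and an expected
count $E_i$ obtained by indirect standardisation: reference rates per
(sex, 5-year age band) stratum are computed from a comparison population —
the whole study region for regional maps, the urban subarea for local maps —
and multiplied into each area's person-years. With an internal comparison
population the calibration identity $\sum_i E_i = \sum_i O_i$ holds exactly,
and the raw standardised incidence ratio is $\hat\theta_i = O_i/E_i$.

Raw SIRs at small-area scale are dominated by Poisson noise (typical $E_i$
here is below ten), so the package smooths them with the BYM hierarchy

$$O_i \sim \mathrm{Poisson}(E_i\,\theta_i), \qquad
\log \theta_i = \alpha + x_i^\top\beta + u_i + v_i,$$

where $u$ is an intrinsic CAR (ICAR) field — each $u_i$ conditionally normal
around the mean of its neighbours with precision $\tau_u d_i$ — carrying
spatially structured risk, $v_i \sim N(0, \tau_v^{-1})$ carries unstructured
risk, and the optional fixed effects $x_i^\top\beta$ allow area-level
covariates (used for the model-based ecological regression below; the plain
mapping fit has no covariates). The ICAR field is identified by a
sum-to-zero constraint. $\Pr(\theta_i > 1 \mid \text{data})$ — the posterior
probability PP — classifies areas into five signal classes at cut-offs
0.90/0.80/0.20/0.10, boundaries belonging to the class below (a PP of
exactly 0.90 is a moderate, not strong, signal).

### Sampler

`fit_bym()` uses Metropolis-within-Gibbs, implemented in C++:

* adaptive single-site random-walk updates for $\alpha$, each $u_i$, each
  $v_i$ and each $\beta_j$ (targets: 44% acceptance for single sites, ~30%
  for global parameters, adapted during burn-in only);
* a global rescale move $u \to c\,u$ with a log-normal multiplier. The field
  amplitude and $\tau_u$ are strongly coupled, which single-site updates
  traverse slowly; the rescale move removes that bottleneck;
* conjugate Gamma updates for $\tau_u$ (shape augmented by half the ICAR
  rank, $n-1$ on a connected graph) and $\tau_v$;
* recentring of $u$ every sweep, transferring the mean into $\alpha$. Under
  the flat prior on $\alpha$ this is an exact, likelihood-preserving
  identifiability move.

Defaults are 4 chains of 20,000 iterations with 10,000 burn-in and thinning
5. Convergence is summarised by split-chain R-hat on $\alpha$ and the log
precisions with a warning above 1.1. Areas without neighbours have $u_i$
pinned to zero (with a warning); a disconnected graph (beyond such islands)
is an error rather than a silent refit. Rows with $E_i = 0$ cannot inform a
ratio and are dropped with a warning.

Priors: Gamma(shape 0.5, rate 0.0005) on both precisions — our concrete
rendering of a minimally informative precision prior — flat on $\alpha$,
$N(0, 10^2)$ on covariate coefficients, Beta(1, 1) on the zero-inflation
weight. The robustness harness in the test suite refits a standard fixture
under two alternative vague settings (Gamma(1, 0.001) and Gamma(0.1, 1e-4))
and checks that every smoothed SIR moves by less than 5%.

### Correctness anchors

The sampler is validated against independent oracles rather than another
MCMC implementation: a conjugate Poisson–Gamma argument for the degenerate
one-area model, and for a 4-area toy a brute-force importance-sampling
evaluation of the same hierarchy (`bym_reference_posterior()`): precisions
integrated out analytically, the 8-dimensional marginal posterior maximised
numerically, and draws taken from a two-component multivariate-t mixture
around the mode. Posterior mean smoothed SIRs agree within 2% relative.

### Zero inflation and model choice

`fit_zip_bym()` replaces the observation model by
$O_i \sim \pi\,\delta_0 + (1-\pi)\,\mathrm{Poisson}(E_i\theta_i)$ with a
global $\pi$, sampled by augmenting structural-zero indicators. Model choice
uses DIC $= \bar D + p_D$, with $p_D = \bar D - D(\text{posterior mean
parameters})$ (plug-in at posterior mean $\theta_i$, and $\bar\pi$ for the
mixture). On data simulated without structural zeros the Poisson model is
preferred in most replicates — the sparse-count sanity check that motivates
keeping the plain Poisson likelihood for mapping.

## Ecological regression: two routes

The headline inequality estimate regresses smoothed incidence on deprivation
quintile. The package ships both of the defensible constructions:

1. **Two-step WLS** (`ecological_regression()`): weighted least squares of
   $\ln \hat\theta_i$ on quintile indicators (Q1 reference), weights
   $1/\mathrm{Var}(\ln\theta_i)$ from the posterior draws (the variance
   plug-in is an argument, since other choices are possible). This is the
   direct transcription of regressing on a smoothed surface. It is also
   structurally conservative: smoothing contracts area-level contrasts
   toward 1, so group ratios are attenuated, and the Wald intervals —
   computed from residual scatter of already-smoothed, spatially correlated
   values — do not propagate that contraction. Treat its estimates as lower
   bounds on gradients and its intervals as descriptive.
2. **Model-based** (`fit_bym(..., covariates = quintile)`): quintile fixed
   effects inside the Poisson linear predictor, the classical ecological
   regression for disease mapping. Credible intervals on $e^{\beta_q}$
   account for smoothing and spatial confounding; in the simulation harness
   this route recovers generative ratios essentially unbiased with
   near-nominal interval coverage, while the two-step route recovers them
   only up to attenuation.

The case-level analysis (`late_stage_logistic()`) fits the late-stage odds
(definitions: stage II–IV, or III–IV) on age band, sex and quintile by
`stats::glm`; reference levels are age 30–34, female, Q5, matching the
tabulation convention of the published margins. Separation and
non-convergence are reported as errors, not silently returned.

## The scan sensitivity check

`kulldorff_scan()` is the classical purely spatial Poisson scan: circular
windows over centroid-ordered areas up to half the total expected count,
log-likelihood ratio
$O_{in}\ln(O_{in}/E_{in}) + O_{out}\ln(O_{out}/E_{out})$ for windows with
elevated inside rate, and Monte-Carlo inference conditioning on the total
count (multinomial redistribution proportional to $E$). Secondary clusters
are reported greedily among non-overlapping windows.
`compare_signal_sets()` summarises agreement with the PP classification as a
Jaccard index; the two methods answer different questions (global cluster vs
per-area exceedance), so qualitative agreement is the expectation, not
identity. Window shape and the maximum-size fraction are parameters because
no canonical setting exists.

## What the generator emulates — and what it does not

`generate_geography()` builds a rectangular rook-adjacency lattice:
adjacency structure is the only geographic input BYM uses, so the simplest
connected planar graph suffices. Median incomes are log-normal
(`sdlog = 0.25`) with a west–east log-linear trend (default 1.0), making
deprivation spatially clustered as in real urban geographies. Quintiles cut
the *areas* (not population) into fifths by income, splitting at ranks
$\lceil kn/5 \rceil$ with ties broken by area id — small areas of this type
are near-equal in population, so area-quintiles and population-quintiles
almost coincide.

`generate_population()` draws area sizes around a mean of 1,600 persons
aged 30+ from a truncated log-normal whose 99% bounds keep area-year totals
inside the 600–2,600 band characteristic of the emulated small-area system,
splits them 1:1 by sex and by a shipped adult age pyramid (a smoothly
declining western-European shape; overridable), over nine calendar years.

`simulate_cases()` is the generative mirror of the smoothing model: ICAR
field plus i.i.d. field on the log scale, stratum Poisson counts expanded to
case rows. Defaults, chosen once:

* stage baselines 20 / 5 / 2 per 100,000 person-years (stages I, II,
  III–IV), with incidence rising log-linearly in age — steeper for later
  stages, so the late-stage share rises with age as in registry data — and a
  1.2× male excess;
* quintile log-effects $(0, .10, .10, .17, .30)$ for stage I (a wealth
  gradient reaching ~1.35× in Q5), $(0, .01, .01, .02, .04)$ for stage II,
  flat for stage III–IV;
* $\tau_u = 50$, $\tau_v = 150$: on the 200-area reference lattice this
  gives a structured field sd of roughly 0.13 and total log-risk sd near
  0.2, so true relative risks span about 0.6–1.6 — the scale on which
  smoothed SIR ranges like 0.5–2.2 arise once a deprivation gradient is
  added over a few thousand areas. The analysis scripts use a stronger
  residual field ($\tau_u = 8$) for the signal-rich regional scenario.

The generator does **not** emulate: irregular area shapes and sizes,
population drift and migration, diagnostic-practice differences between
areas, income–age correlation, spatio-temporal trends in risk, or melanoma
biology (subtypes, growth). Passing tests therefore certify the inferential
machinery under the model's own assumptions — they do not certify that real
registry data satisfy those assumptions.

## Numerical and design choices

* ICAR simulation uses the eigen-decomposition of the graph Laplacian,
  sampling only the non-null eigenspace; draws sum to zero exactly.
* SIRs with $O_i = E_i = 0$ are recorded as missing and excluded from
  smoothing with a warning; $E_i = 0$ with $O_i > 0$ is an error.
* The smoothed SIR summary is the posterior mean (median also reported).
* Direct standardisation pools sexes by default (a by-sex option exists) and
  uses the 2013 European Standard Population restricted to the thirteen
  bands 30–34 … 90+, renormalised; the weights are package constants and
  user-overridable. Empty age strata contribute zero with a warning.
* Stage recoding boundaries: thickness ≤ 1.0 mm is stage I; 1.1–2.0 mm is
  stage I without ulceration, II with; > 2.0 mm is II; any nodal or distant
  spread is III–IV regardless of thickness. Missing thickness without spread
  is unstageable — an error by default, a counted exclusion in
  `read_cases()`.
* Concordance between stages selects signalling areas at PP > 0.80 /
  < 0.20 (strong + moderate) by default; the threshold is an argument
  because either convention is defensible.
* Problem sizes in the shipped tests and scripts (200-area lattices, 2-chain
  runs of 3,000–8,000 iterations, 8–20 simulation replicates) are chosen as
  the smallest at which the checked properties are stable; production maps
  should use the 4 × 20,000 defaults.

## Worked example

```{r}
library(stagemap)

geo   <- generate_geography(10, 20, income_spatial_trend = 1, seed = 1)
pop   <- generate_population(geo, mean_area_pop = 1600, n_years = 9, seed = 2)
cases <- simulate_cases(pop, geo, risk_params(), seed = 3)

sir <- compute_sir(expected_counts(cases, pop, stage = "I"))
fit <- fit_bym(sir, geo$adjacency)
head(fit$summary)

signals <- classify_signals(fit)
table(signals$class)

quint <- setNames(as.character(geo$areas$quintile), geo$areas$area_id)
ecological_regression(fit, quint)                     # two-step WLS
fit_bym(sir, geo$adjacency,
        covariates = geo$areas$quintile)$covariate_summary  # model-based
```

The numbered scripts under `analysis/` run the same chain end-to-end on a
simulated region and write all tables under `results/`.

## Known limitations

* The two-step ecological regression attenuates gradients by construction
  (see above); cross-quintile ratios from that route are conservative.
* ICAR scale is graph-dependent: a given $\tau_u$ implies different field
  amplitudes on different lattices, so generator precisions are calibrated
  to the reference lattice, not universal constants.
* The scan statistic uses circular windows on centroids; elongated clusters
  are found only piecewise.
* Single global zero-inflation weight; no area-level zero-inflation
  covariates.
* No spatio-temporal smoothing: years are pooled into one map per stage.
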