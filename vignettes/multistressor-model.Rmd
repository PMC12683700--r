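---
title: "A spatially explicit state-space model for health, vital rates and growth under multiple stressors"
author: "stressorweave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spatially explicit state-space model for health, vital rates and growth under multiple stressors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressorweave)
```

## The problem

North Atlantic right whales are exposed simultaneously to entanglement in
fixed fishing gear, vessel strikes, and climate-driven variation in the
availability of their copepod prey.  Because the population is small,
long-lived, and slow to reproduce, population-level consequences of these
stressors cannot be detected quickly from counts alone.  The package
implements a Population-Consequences-of-Multiple-Stressors style analysis:
individual *health* is a latent state that integrates stressor effects and
drives survival and calving, while somatic growth toward an individual
asymptotic length modulates female reproduction.  Exposure to each stressor
is resolved in space and time by combining regional stressor surfaces with
each individual's occupancy distribution over regional polygons.

All data structures are desk-scale stand-ins: the real sightings database is
confidential, so the package ships a forward simulator
(`simulateDataset()`) that generates datasets with the same structure and
known truth.

## Spatial structure and occupancy

The population's range is collapsed into regional polygons (7 by default;
any number of at least 2 is supported, and tests run with 3).  Time advances
in three-month steps, with the December–February season assigned to the year
containing January, and a configurable era break (default 2010) capturing
the observed distribution shift.

Occupancy `z` — the proportion of a step an individual spends in each
region — is estimated two ways:

* **v1 (data-driven)**: a Dirichlet model of per-individual-quarter
  compositional presence, stratified by demographic class, season and era.
  Compositions are built from sighting counts with additive smoothing
  (+0.5 per region) because sparse sightings cannot identify true zero
  presence.  Estimation is by fixed-point maximum likelihood on the digamma
  moment condition, with a conjugate-style estimate (`1 +` count sums) for
  strata under 5 compositions and a symmetric `alpha = 1` fallback for empty
  strata.  Maximum likelihood is the standard, testable estimation choice
  for Dirichlet compositions.
* **v2 (model-based)**: the relative whale density surface is taken to
  describe the average individual, rescaled by the empirical class
  proportions per region-season and renormalized.  Density predictions exist
  only from 2003; earlier steps reuse the 2003–2009 per-season mean.
  Regions outside the density model's coverage are filled by scaling
  sighting counts with the sightings-to-abundance ratio of a covered
  reference region.

A third, non-spatial formulation (v3) replaces occupancy with uniform
weights and population-level annual covariates, and exists mainly so
combined-effect hypotheses can be compared across formulations.
Whether occupancy should enter the MCMC as posterior draws or plug-in means
is genuinely open; the plug-in mean is the default and posterior draws are
available through `occupancyV1(..., draw = TRUE)`.

## Exposure

With rescaled risk surfaces (each surface is divided by its global maximum,
the normalizer that preserves the surface's relative spatiotemporal
structure), per-step exposure is:

* entanglement: `p_ent = iota1 * sum_l z_l G_l e_l`, where `e` is a
  landings-derived backcast multiplier (1 from 2015 onward, landings-ratio
  scaled before);
* vessel strike: `logit(p_r,l) = logit(iota2 * AIS_l) + v * (2019 - year)`
  per region, then `p_strike = sum_l z_l p_r,l`;
* prey: `prey' = sum_l z_l prey_l`, averaged within each year and
  standardized by the mean and SD across all annual means.  The
  standardized annual value affects health in the June–August step.

The conversion coefficients have constrained supports so every probability
is valid; values outside the support raise errors rather than being clipped,
so an invalid configuration is always visible.

## Health, events and combined effects

Health is a bounded random walk on (0, 100] with Gaussian increments
(`sigmaH` per step, clamped at a floor of 0.01).  The scale follows the
visual-health-assessment literature; effect sizes are interpretable as
points on that scale.  Each step's drift adds:

* intrinsic effects: the calf-to-juvenile transition (once) and a per-step
  lactation cost during the calf's birth year;
* a new entanglement's immediate effect by severity (minor/moderate/severe)
  *plus* one step of the prolonged gear-carrying effect — the prolonged
  effect deliberately does not apply separately in the event step, which
  breaks the confounding between immediate and prolonged effects;
* the prolonged gear effect for every later step carrying gear;
* a strike's effect by injury class (superficial/shallow/deep/blunt);
* the prey effect in the summer step;
* the single active interaction term: prey modifying the gear, severity or
  injury effects, or prior-entanglement history (count, any, any within 8
  steps — the 2-year window with an inclusive boundary) modifying a new
  event's effect.

Interactions enter additively on the health scale (`effect = main +
gamma * preyStd`); reported interaction parameters are single coefficients
per pairing, and one hypothesis is active per fitted model, mirroring the
one-hypothesis-at-a-time experimental design.  Positive coefficients mean an
improvement in health.

## Growth and calving

Length follows a von Bertalanffy curve `L = A_i - (A_i - L0) exp(-k age)`
with shared `k`, `L0` and individual asymptotes `A_i ~ N(A_mean, sigmaA)`
truncated above `L0`.  The asymptote mean can carry a birth-year trend
(centered at 1980) and the covariate block of the active length hypothesis
(prolonged early-life health over 15/10/5/2/1-year windows, mother's health
at or during lactation, mean prey and entanglement status and their product,
mother's entanglement status).  Covariates act on the asymptote rather than the growth rate: the
documented decline in this species is a decline in maximum attained length,
which the asymptote captures directly.  Males are modelled too (they inform
the trend); only female length feeds calving.

Survival uses the hazard form of the complementary log-log link:
`lambda = exp(aS - bS h)` per quarter and `theta = exp(-lambda)`, so
quarterly hazards add to annual hazards and the identical `lambda` drives
the projections.  Because this link is nonlinear, health-additive insults
are non-additive on the survival scale — a property pinned by a regression
test.  Calving for available females (mature, and at least 2 full calendar
years after the previous calving) is logistic in mean annual health
(centered at 70) and length (centered at the adult-female reference).

## Observation models

Sightings are Bernoulli with region-by-season detection probability;
ordinal health scores follow an ordered-probit model with fixed, strictly
increasing cutpoints on the health scale (four variables with four
categories each by default — the cutpoints anchor the latent scale);
photogrammetric lengths are Normal with platform-specific SD; observed
events are conditioned on; and cryptic mortality is handled by allowing at
most one unobserved terminal entanglement and one terminal strike after the
last sighting, with event-time mass proportional to exposure and class drawn
from categorical priors.  The exposure-weighted time prior is this
package's modelling choice; a uniform prior is the obvious alternative and
differs only when post-sighting exposure varies strongly over steps.

## Inference

The joint model — latent health per individual-step, event effects, the
hazard-rate survival likelihood and the ordinal score likelihood — is fitted
by MCMC in JAGS through `rjags`, the engine family in which this model class
was originally developed; discrete severities of observed events are data,
and the hazard is centered at health 70 to decorrelate the intercept and
slope.  `runMCMC()` seeds every chain deterministically, and computes
split-chain R-hat and effective sample sizes; runs with any R-hat above 1.1
are flagged non-converged.  Combined effects are summarized exactly as the
field reports them: posterior median, 95% credible interval, sign, and
whether the interval overlaps zero (`summarizeInteractions()`).

The pure-R `jointLogDensity()` mirrors the composed density so tests can
verify the composition term by term against independently computed
components.

## The synthetic-data generator

`generateSurfaces()` produces positive region-by-step fields with the
structural features of the study system: northern-elevated entanglement
risk, a vessel-traffic field with an exponential temporal trend (default
+2%/yr), a summer-peaked prey field with a post-2010 regime shift (default
−35% in the mean) and log-normal inter-annual noise, and a seasonal
whale-density cycle that shifts north after the era break.
`generatePopulation()` runs the full generative model forward — occupancy
draws, exposure, events, health, growth, survival, calving with pedigree —
and `generateObservations()` masks the truth through the observation
models.

Rates are set to field-realistic values and then left alone: the
entanglement conversion coefficient gives annual entanglement probabilities
in the 10–25% range reported by scar-based studies; gear is carried for a
geometric number of steps with mean about one year; scar-based entanglement
detection is high (0.9) while strike detection is lower (0.5); carcass
recovery is 0.3; baseline adult survival at the uninjured health mean is
about 97% per year.  What the simulator does *not* emulate: fine-scale
movement, effort-varying detection, cause-specific carcass recovery,
mid-life cryptic events, and density dependence.  Passing recovery tests on
these data therefore show the estimation machinery is self-consistent, not
that the real data would identify the same effects.

## Parameter-recovery experiment

`runRecoveryExperiment()` is the package's simulation study: 10 replicates,
each simulating 3 regions x 30 years from ~20 founders (growing to roughly
40–80 individuals) with a known positive gear-by-prey interaction
(`gamma = 1.5` health points per prey SD; positive gamma means poor prey
worsens the gear-carrying cost), then fitting the joint health–survival
model (single chain, 350 warmup + 350 sampling draws) and the growth model.
Problem sizes and chain lengths are the package's desk-scale choices; the
monitored checks are the sign of the interaction's posterior median and 95%
credible-interval coverage of the generating survival slope, growth rate
and asymptote across replicates.

## Viability projections

`project()` implements the four modifications that connect the fitted model
to a hazard-rate viability tool: (1) survival through hazards with the
uninjured-health distribution, (2) calving as a function of health, (3)
length dynamics feeding calving, and (4) temporal autocorrelation in
health.  The fitted random walk is nonstationary and unsuitable for
forward prediction, so the projector uses a mean-reverting AR(1) (default
autocorrelation 0.7) anchored at the uninjured mean.  Scenarios cross an
entanglement-risk multiplier (1, 0.5, 0), a prey regime (historical
1990–2009 vs low 2010–2019), and an asymptotic-length regime (decline to a
10 m floor, stabilize at ~11.8 m, recover toward ~14.0 m), over 100 years
with 1000 draws by default; vessel-strike levers exist but are excluded
from the default grid.  Every result object carries a demonstration-grade
flag: projections illustrate the machinery and must not inform management.

## Numerical choices and degenerate inputs

* Dirichlet ML uses Minka's fixed-point iteration with a Newton inverse
  digamma; degenerate all-at-one-vertex strata return a vertex-concentrated
  alpha with a warning.
* Health clamps to [0.01, 100]; trajectory likelihoods use truncated-Gaussian
  increments.
* `AIS = 0` maps to strike probability 0 (the logit limit); `iota2 * AIS = 1`
  errors as an out-of-support coefficient.
* Standardization with fewer than two distinct annual prey means, constant
  anomaly series in the prey backcast, and all-zero occupancy weights are
  errors, never silently patched.
* Missing surface cells are filled by region-season climatology and the
  policy is recorded in the object's metadata.

## Known limitations

Occupancy enters the fit as a plug-in, so spatial uncertainty is not
propagated into exposure posteriors.  Ordinal cutpoints are fixed
observation constants rather than estimated.  Individuals never seen again
are right-censored at the last sighting in the fitted likelihood; the
terminal-event machinery is implemented and tested at the function level
but not sampled inside the reduced desk-scale MCMC.  Mid-life undetected
events are unmodelled, which inflates the apparent process noise when event
detection is poor.  These are the same structural compromises the original
analysis acknowledges, reproduced here at a scale where every component can
be verified against known truth.
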