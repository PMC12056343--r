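---
title: "Methods: diel activity timing and variability from automated radio telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diel activity timing and variability from automated radio telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`dielscope` estimates five activity traits of radio-tagged songbirds from
automated receiver logs — daily onset of activity, daily end of activity,
duration of diurnal activity, diurnal activity level and nocturnal activity
level — and models how urban and forest populations differ in those traits,
both in their means and in their between- and within-individual variances.
The pipeline is

1. **signal differentials**: raw per-receiver signal strengths on a 3-min
   scan grid are differenced (`|s_t - s_{t-1}|`) per receiver and averaged
   across a site's receivers;
2. **changepoint detection**: a two-block Gaussian maximum-likelihood split
   locates the daily transition between the quiet (roosting) and noisy
   (active) signal regime inside solar-anchored windows;
3. **activity scoring**: each 3-min differential above 10 dB counts as
   an active interval; fixed clock windows (10:00–16:00, 22:00–02:00)
   give binomial day- and night-activity counts;
4. **hierarchical models**: Bayesian location–scale mixed models contrast
   habitats in means and in habitat-specific between-individual (bird) and
   within-individual (residual / observation-level) variances, from which
   repeatability and day–night activity correlations follow.

A synthetic-telemetry generator with known ground truth makes every stage
testable without field data.

# Signal model and preprocessing

The premise of movement inference from a fixed receiver array is that a
static bird yields a constant received signal (up to receiver noise), while
a moving bird relocates relative to each antenna, so consecutive readings
jump. The *signal differential* `d_t = |s_t − s_{t−1}|` is therefore a
movement proxy.

Choices a user should know:

* **Grid and snapping.** Slots are anchored at local civil midnight; slot
  `s` covers `[180 s, 180 (s+1))` seconds. Receiver timestamps jitter, so
  they are floored to the slot boundary; duplicate (tag, receiver, slot)
  rows collapse to the strongest signal.
* **Pairs, not gaps.** `d_t` is defined per receiver only when slots `t`
  and `t−1` were both detected on that receiver. Differencing across a gap
  would inflate differentials, so gaps break the pair.
* **Site averaging over available receivers.** The site-level `d_t`
  averages the receivers with a defined pair at `t`. Whether the original
  field protocol treated missing receiver pairs as absent or as zero is not
  documented; absent is used because zeros would fabricate inactivity.
* **Coverage.** A window's coverage is the fraction of its slots with a
  defined `d_t`. A slot belongs to a window iff its *start* lies in the
  half-open window, so a 6-h window holds exactly 120 slots even when its
  solar-anchored bounds fall between grid points. Retention rules are
  strict `> 0.75` for timing windows and inclusive `>= 0.50` for activity
  windows, following the phrasing "more than 75%" / "at least 50%".

# Solar windows

Sunrise and sunset are computed from the NOAA solar-position equations at
solar zenith 90.833° (standard refraction plus solar radius — the civil
sunrise-table definition), in the site's civil local time, including DST.
Accuracy against an independent, event-time-iterating ephemeris
implementation is below one minute at the study latitudes (the test suite
enforces two minutes). The analysis windows are: onset `[sunrise − 4 h,
sunrise + 2 h)` (6 h), end `[sunset − 4 h, sunset + 4 h)` (8 h), diurnal
`[10:00, 16:00)`, nocturnal `[22:00, 02:00)` keyed to the night's starting
date. Relative timing traits are event minus solar anchor, in hours,
negative meaning before the anchor.

# Changepoint estimation

For the differential series inside a window (missing slots removed, index
map retained), every admissible split `k` divides the series into two
blocks; each block gets a Gaussian fit at its MLE and `L(k)` is the summed
block log-likelihood. The estimate is the earliest maximiser of `L(k)`; the
transition time is the first slot of the second block.

Numerical choices:

* **Minimum block** of 5 slots (15 min): a Gaussian MLE on fewer points is
  meaningless; the source protocol is silent, so this is a package choice.
* **Variance floor** of `1e-6` dB²: constant blocks otherwise give
  infinite likelihood. The floored variance enters the density while the
  unfloored MLE enters the quadratic term, so flat profiles stay flat.
* **Ties** resolve to the earliest split at a relative tolerance of
  `1e-9`, so exact ties survive cumulative-sum rounding; earliest is the
  conservative (earlier-onset) completion.
* **Support** (max minus median of the profile) is recorded with every
  estimate. No hard support threshold is applied — flat, transition-free
  days are flagged by low support rather than silently dropped, since the
  original protocol documents no exclusion rule for them.

The whole scan runs in O(n) via cumulative sums; the test suite proves
exact equivalence with independent exhaustive enumeration.

**Broken-stick validation.** A second estimator fits, on a discrete
breakpoint grid, a flat Gaussian segment followed by a linear trend, with a
uniform breakpoint prior and conjugate normal-inverse-gamma coefficient
priors on the standardized response (prior variance 100, IG(2, 1)); the
per-breakpoint marginal likelihood is closed-form, so the breakpoint
posterior is exact. Its posterior median is reported, with a `wide` flag
when the central 95% interval spans more than half the candidate range.
This method is for cross-validation reports only; the likelihood split is
the primary estimator.

# Activity levels

A slot is *active* when `d_t > 10` dB and *inactive* when `d_t <= 10`;
missing slots are unscored. The defining clauses ("higher than 10 dB",
"lower than 10 dB") are both strict, leaving equality open; inactive is the
conservative completion. One threshold serves all six species, as validated
in earlier field work with this tag family. Proportions are computed over
scored slots — not the whole window — so dropout is never read as rest, and
the underlying counts are kept because the binomial models consume counts.
Thresholding uses the site-averaged differential, consistent with the
timing stages.

# Hierarchical models

## Timing traits

For relative onset, relative end and duration (hours), the model is a
heteroscedastic linear mixed model:

* fixed effects: habitat, species, season, year, standardized daily minimum
  temperature and precipitation, habitat × species, habitat × season (sex
  models add sex and sex × {habitat, season, species} for the three
  sexable species);
* random intercepts: site and calendar date (crossed, date shared across
  sites);
* **habitat-specific bird-intercept SDs** `sigma_B[habitat]` — the
  between-individual variances — and **habitat-specific residual SDs**
  `sigma_W[habitat]` — the within-individual variances.

Priors are pinned explicitly (a software-relative "default prior" is not
reproducible): half-t(3, 2.5 sd(y)) on `sigma_B` and `sigma_W`,
half-t(3, 0.5 sd(y)) on the site and date SDs, and normal(0, 10 sd(y)) on
fixed effects. The tighter site/date scale is deliberate: with two sites
per habitat the site variance has about two identified degrees of freedom,
and a unit-scale half-t tail would dominate the habitat contrasts; site and
date are nuisance intercepts here, not inferential targets. Fixed-effect
priors are conjugate normals rather than Student-t, which keeps every
conditional in closed form; at 10 sd(y) they are effectively flat.

**Sampler.** The model is fully conjugate, so it is fitted by a
purpose-built blocked Gibbs sampler: one exact multivariate-normal draw of
*all* location parameters per sweep (fixed effects, site, date and bird
intercepts jointly, using a Schur complement on the diagonal bird block),
then inverse-gamma draws of the variance components through the Huang–Wand
half-t mixture. Joint location draws are essential — one-at-a-time scans
random-walk along the habitat/site/bird-mean ridge. Near-zero variance
components still mix slowly (the usual funnel), so each sweep adds
multiplicative Metropolis rescale moves `(u, sigma) -> (c u, c sigma)` at
three step sizes for the site, date and per-habitat bird blocks. Four
chains of 2,000 kept draws after 500 warm-up sweeps give split R-hat below
1.01 on the designs used here; the defaults are configurable. Chains are
initialized from dispersed variance draws, and the test suite cross-checks
the posterior against an independently coded JAGS fit of the same model
and priors.

## Activity levels

Diurnal and nocturnal counts are binomial GLMMs (logit link) with the same
fixed and random structure plus a **habitat-specific observation-level
random effect** (OLRE), which supplies the within-individual variance
component a binomial likelihood lacks. The bivariate model joins both
windows: bird effects and OLREs become bivariate normal per habitat, with
SDs and correlations `rho_B[habitat]`, `rho_W[habitat]` — the
within-individual correlation is the direct test of a day–night activity
trade-off. These non-conjugate models are sampled with JAGS (with its
`glm` block-sampler module); priors mirror the timing model on the logit
scale (half-t(3, 2.5), normal(0, 5) on coefficients). Population-level
activity proportions per habitat are inverse-link marginal predictions
averaged over each habitat's observed covariate rows.

## Derived quantities and inference

Per posterior draw: variance-difference contrasts `sigma_B[urban] −
sigma_B[forest]` and `sigma_W[urban] − sigma_W[forest]`; repeatability
`R = sigma_B^2 / (sigma_B^2 + sigma_W^2)` per habitat and its habitat
difference; urban − forest marginal contrasts per species
(season-averaged) and per season (species-averaged). Summaries are
posterior medians with central 95% credible intervals, and the inference
rule is: evidence for an effect iff the 95% CrI excludes zero. No p-values
appear anywhere.

The repeatability denominator excludes the site and date variances; the
source protocol's phrasing ("between-individual variation over total
phenotypic variation") does not settle this, but the magnitude of its
printed estimates is consistent with the two-component form, and the
two-component ratio is the quantity the habitat-specific variance pairs
identify cleanly.

# The synthetic generator

The generator emulates the study design: six passerine species, two urban
and two forest sites (real Glasgow / Loch Lomond coordinates), two to four
receivers per site scanning every 180 s, pre-breeding (Feb–Apr) and
post-breeding (Sep–Nov) seasons. Each bird draws one between-individual
deviation (per-habitat SD) for onset and for end; each bird-day adds a
within-individual deviation; true onset/end anchor to sunrise/sunset plus
species baselines and per-species urban shifts. Within `[onset, end)` the
bird is active per slot with the habitat's diurnal probability (daytime
rest gaps); in the nocturnal window with the habitat's nocturnal
probability.

Default parameters are the study conditions: urban onset shifts of −33 and
−30 min for blackbird and robin (smaller for the other species), onset
between-individual SDs 0.452/0.350 h and within-individual SDs
1.035/0.776 h (urban/forest) — jointly chosen so the implied
variance-difference contrasts (+0.102 and +0.259 h) and repeatabilities
(0.159 urban, 0.169 forest) reproduce the study-scale structure — and
nocturnal per-slot activity 4.1% (urban) / 1.6% (forest).

**Signal generation.** Movement in an active slot displaces the bird, so
each receiver's latent level performs a jump of magnitude uniform in
`[step, 2 step]` dB with random sign (reflected toward baseline beyond
±40 dB); while static the level holds. The latent level persists across
slots and days. This random-walk form is what makes the differential a
*per-slot* movement indicator: only active slots produce a large `d_t`,
so the scored activity proportion is an unbiased estimate of the
configured activity probability. An i.i.d.-deviation form would instead
mark the slot after each active slot as active too. Receiver baselines are
drawn once per bird–receiver pair in `[−120, −60]` dB, so differentials,
not absolute strengths, carry the signal. Receiver noise (default 2 dB SD)
and a 20 dB minimum step give a step-to-noise ratio of 10; with these
values active and inactive slots are separable at the 10 dB threshold with
error well below 1%. Detection dropout is independent per slot and
receiver (default 0.9); the field distribution of dropout is not published,
so this is an explicit stand-in.

Randomness is organized as named substreams keyed by purpose and unit
(bird, bird–receiver, bird–date, site), derived from one master seed:
identical configs reproduce byte-identical studies, and adding birds never
perturbs existing birds' draws.

Climate covariates are site-level AR(1) series around seasonal means
(minimum temperature: 2.5 °C pre-breeding / 7 °C post-breeding, phi = 0.7;
precipitation truncated at zero). They exist to exercise the model
covariates, not to drive behaviour.

**What the generator does not emulate** — and hence what passing tests do
not certify about field data: radio propagation and antenna directionality,
spatial movement and distance-dependent signal loss, bout-structured
activity (activity is exchangeable within the active phase), structured
dropout (e.g. receiver outages), weather-dependent behaviour, and
species-specific signal signatures. Recovery results on synthetic data are
a check of the *estimators*, not a validation of the biological threshold
choices.

# Problem sizes and runtime choices

The package's own validation runs at desk scale, chosen to keep the full
suite in minutes while leaving the Monte Carlo error far below every
tolerance asserted: changepoint recovery uses 520 synthetic bird-days at
step/noise 10; variance-component recovery uses 20 replicate fits of 150
birds × 20 days with 4 chains × 2,000 kept draws; the bivariate model uses
60 birds × 12 days. The acceptance script simulates 264 birds over 15 days
(the tagged-cohort scale of the study design) and fits the onset model
once. MCMC defaults (4 × 2,000 kept draws for the Gibbs sampler) replace
the original three 50,000-iteration thinned chains; the effective sample
sizes are comparable and all settings are arguments.

# Known limitations

* With two sites per habitat, habitat contrasts are identified through the
  site prior; the tighter site prior scale is a documented choice, and
  sensitivity to it should be checked when porting to other designs.
* The changepoint estimator assumes one dominant transition per window;
  days with fragmented onsets (e.g. interrupted dawn activity) yield a
  low-support estimate rather than a multi-transition description.
* Binomial OLRE variances are on the logit scale; comparing them with the
  timing-trait variances (hours) is not meaningful.
* The generator's dropout and bout structure are idealized as independent
  Bernoulli processes; retention-rule behaviour under structured outages
  is exercised only by the engineered-dropout fixtures.
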