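# dielscope

Diel activity timing and variability of radio-tagged birds, from raw
automated-telemetry logs to heteroscedastic Bayesian population contrasts.

## The problem

Automated radio receivers log the signal strength of each tagged bird every
3 minutes. When a bird is static (roosting) its received strength is
constant up to noise; when it moves, the strength jumps. The absolute
change between consecutive scans — the **signal differential**
`d_t = |s_t − s_{t−1}|`, averaged over a site's receivers — is therefore a
movement proxy from which five traits are derived per bird-day:

* **onset / end of activity**: the split `k*` maximising the two-block
  Gaussian log-likelihood
  `L(k) = ℓ(x_1..k) + ℓ(x_k+1..n)` over the differentials in a solar
  window (onset: sunrise − 4 h to sunrise + 2 h; end: sunset ± 4 h),
  reported relative to sunrise/sunset (negative = earlier);
* **duration** of diurnal activity = end − onset;
* **diurnal / nocturnal activity levels**: the share of 3-min intervals
  with `d_t > 10` dB inside 10:00–16:00 and 22:00–02:00.

Estimates are retained only from windows with > 75% detection coverage
(timing) or ≥ 50% (levels). Population structure is then modelled with
location–scale hierarchical models, e.g. for a timing trait `y_ij` of bird
`j` in habitat `h`:

    y_ij = x_ij'β + site + date + b_j + e_ij,
    b_j ~ N(0, σ²_B,h(j)),   e_ij ~ N(0, σ²_W,h(ij))

with habitat-specific between-individual (σ_B) and within-individual (σ_W)
standard deviations, giving per-draw variance contrasts
(σ_B,urban − σ_B,forest, σ_W,urban − σ_W,forest), repeatability
`R_h = σ²_B,h / (σ²_B,h + σ²_W,h)`, and urban − forest marginal contrasts
per species and season. Activity levels use binomial GLMMs with
habitat-specific observation-level random effects, and a bivariate
diurnal–nocturnal model estimates between- and within-individual day–night
correlations per habitat. Evidence for an effect means the 95% credible
interval excludes zero.

The timing model is fitted by a purpose-built blocked Gibbs sampler (joint
draw of all location parameters, half-t variance priors via the Huang–Wand
mixture, funnel rescale moves); the binomial models run on JAGS. A
synthetic-telemetry generator with known ground truth (per-bird diel square
waves anchored on sunrise/sunset, per-receiver latent signal walks,
detection dropout) backs the test suite. See the methods vignette
(`vignettes/diel-activity-methods.Rmd`) for models, priors and numerical
choices.

## Worked example

```r
library(dielscope)

cfg   <- sim_config(n_birds_per_species_per_habitat = 6, n_days = 12, seed = 42)
study <- simulate_study(cfg)                       # detections + metadata + truth
est   <- estimate_activity(study$detections, study$birds, study$solar)
lev   <- activity_levels(study$detections, study$birds, study$solar)

head(est$estimates[, c("bird_id", "date", "relative_onset_h",
                       "relative_end_h", "duration_h")], 3)
#>          bird_id       date relative_onset_h relative_end_h duration_h
#> 1 u_blackbird_01 2020-02-15       -0.8156650   0.8722897202      11.30
#> 2 u_blackbird_01 2020-02-16       -0.8276396   0.5359839828      11.05
#> 3 u_blackbird_01 2020-02-17       -2.0392648  -0.0002696531      11.80
```

`u_blackbird_01` started activity about 49 min before sunrise on 15 Feb
and ended it 52 min after sunset: an 11.3-h active day. Pooled activity
levels recover the configured nocturnal rates (urban 4.0%, forest 1.5%
here). Fitting the onset model:

```r
md  <- merge(est$estimates, study$birds[, c("bird_id","species","habitat","sex")],
             by = "bird_id")
md  <- merge(md, study$climate, by = c("site_id", "date"))
md$season <- cfg$season; md$year <- cfg$year
fit <- fit_timing_model(md, "relative_onset_h", seed = 1)
fit
#> dielscope timing model fit ( gibbs ), response: relative_onset_h
#> 864 observations; 4 chains x 2000 draws
#> max R-hat: 1.0089 (converged)
#>        parameter median   q2.5 q97.5 rhat  ess
#> 1     sigma_site  0.186 0.0169 0.844 1.01  860
#> 2     sigma_date  0.113 0.0213 0.248 1.00 1064
#> 3  sigma_B_urban  0.455 0.3051 0.660 1.00 2494
#> 4 sigma_B_forest  0.281 0.1592 0.430 1.00 1875
#> 5  sigma_W_urban  1.046 0.9750 1.124 1.00 6112
#> 6 sigma_W_forest  0.818 0.7634 0.879 1.00 5818

variance_contrasts(fit)
#>        contrast     median        q2.5     q97.5 evidence
#> 1 delta_sigma_B 0.17341064 -0.04001167 0.4214468    FALSE
#> 2 delta_sigma_W 0.22790241  0.13588181 0.3257091     TRUE
#> 3       delta_R 0.05235855 -0.08975196 0.2079017    FALSE

habitat_contrasts(fit, "species")[1:2, ]
#>     species     median      q2.5      q97.5 evidence
#> 1 blackbird -1.0837796 -1.949531 -0.2491762     TRUE
#> 2  blue_tit -0.2262909 -1.078948  0.6241765    FALSE
```

Urban birds of this small synthetic cohort are detectably *less
consistent* day to day than forest birds (the within-individual SD is
0.23 h larger, CrI excluding zero), urban blackbirds start about an hour
earlier than forest blackbirds, and forest onset repeatability is ~0.11.
`run_pipeline(cfg, out_dir = "out")` performs all stages (plus optional
GLMM fits) in one call and writes CSV artifacts and a count-reconciling
manifest; `inst/scripts/dielscope` wraps simulate/run/windows for the
shell.

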