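# Hierarchical models: equivariance contracts, repeatability identities,
# contrasts, diagnostics, and an independent MCMC cross-check.

small_traits <- function(seed = 5) {
  simulate_timing_traits(n_birds_per_habitat = 24, n_days = 8, seed = seed)
}

test_that("shifting all responses moves only the intercept; scaling scales all SDs", {
  d <- small_traits()
  f0 <- fit_timing_model(d, "y_h", chains = 2, iter = 800, warmup = 300,
                         seed = 2)
  d1 <- d
  d1$y_h <- d$y_h + 1
  f1 <- fit_timing_model(d1, "y_h", chains = 2, iter = 800, warmup = 300,
                         seed = 2)
  s0 <- posterior_summary(f0)
  s1 <- posterior_summary(f1)
  sd_pars <- grep("^sigma_(B|W)", s0$parameter)
  expect_equal(s1$median[sd_pars], s0$median[sd_pars], tolerance = 0.02)
  i0 <- s0$median[s0$parameter == "(Intercept)"]
  i1 <- s1$median[s1$parameter == "(Intercept)"]
  expect_equal(i1 - i0, 1, tolerance = 0.1)

  d2 <- d
  d2$y_h <- d$y_h * 2
  f2 <- fit_timing_model(d2, "y_h", chains = 2, iter = 800, warmup = 300,
                         seed = 2)
  s2 <- posterior_summary(f2)
  expect_equal(s2$median[sd_pars] / s0$median[sd_pars], rep(2, 4),
               tolerance = 0.06)
  # repeatability is invariant under scaling
  expect_equal(repeatability(f2, "forest")$median,
               repeatability(f0, "forest")$median, tolerance = 0.04)
})

test_that("repeatability identities hold draw by draw", {
  fake <- structure(list(
    draws = cbind(sigma_B_urban = rep(1, 100), sigma_W_urban = rep(1, 100),
                  sigma_B_forest = runif(100, 0.1, 2),
                  sigma_W_forest = runif(100, 0.1, 2)),
    chain = rep(1:2, each = 50)
  ), class = "diel_fit")
  r <- repeatability(fake, "urban")
  expect_true(all(r$draws == 0.5))
  expect_equal(r$median, 0.5)
  # sigma_B -> 0 forces R -> 0
  fake$draws[, "sigma_B_forest"] <- 0.0
  expect_true(all(repeatability(fake, "forest")$draws == 0))
})

test_that("posterior matches an independent MCMC engine on the identified variance components", {
  d <- small_traits(seed = 23)
  fit <- fit_timing_model(d, "y_h", chains = 2, iter = 2000, warmup = 500,
                          seed = 3)
  g <- posterior_summary(fit, c("sigma_B_urban", "sigma_B_forest",
                                "sigma_W_urban", "sigma_W_forest"))

  # same model and priors, coded independently for JAGS
  y <- d$y_h
  A <- 2.5 * sd(y)
  An <- 0.5 * sd(y)
  des <- fit$design
  birdf <- factor(d$bird_id)
  dl <- list(y = y, X = des$X, N = length(y), P = ncol(des$X),
             site = as.integer(factor(d$site_id)),
             date = as.integer(factor(as.character(d$date))),
             bird = as.integer(birdf),
             hab = ifelse(d$habitat == "urban", 1, 2),
             habb = ifelse(tapply(d$habitat, as.integer(birdf), `[`, 1) ==
                             "urban", 1, 2),
             Ns = length(unique(d$site_id)),
             Nd = length(unique(d$date)), Nb = nlevels(birdf),
             tA = 1 / A^2, tAn = 1 / An^2,
             tb = 1 / (10 * max(sd(y), 1))^2)
  mstr <- "model{
    for(i in 1:N){ y[i] ~ dnorm(inprod(X[i,],beta)+u[site[i]]+v[date[i]]+b[bird[i]], tau_W[hab[i]]) }
    for(j in 1:Nb){ b[j] ~ dnorm(0, tau_B[habb[j]]) }
    for(s in 1:Ns){ u[s] ~ dnorm(0, pow(sigma_site,-2)) }
    for(dd in 1:Nd){ v[dd] ~ dnorm(0, pow(sigma_date,-2)) }
    for(k in 1:P){ beta[k] ~ dnorm(0, tb) }
    for(h in 1:2){ sigma_B[h] ~ dt(0, tA, 3) T(0,); tau_B[h] <- pow(sigma_B[h],-2)
                   sigma_W[h] ~ dt(0, tA, 3) T(0,); tau_W[h] <- pow(sigma_W[h],-2) }
    sigma_site ~ dt(0, tAn, 3) T(0,)
    sigma_date ~ dt(0, tAn, 3) T(0,)
  }"
  m <- rjags::jags.model(textConnection(mstr), dl, n.chains = 2,
                         n.adapt = 500, quiet = TRUE)
  update(m, 1000, progress.bar = "none")
  s <- rjags::coda.samples(m, c("sigma_B", "sigma_W"), 4000,
                           progress.bar = "none")
  j <- summary(s)$quantiles[, "50%"]
  expect_equal(unname(g$median),
               unname(j[c("sigma_B[1]", "sigma_B[2]",
                          "sigma_W[1]", "sigma_W[2]")]),
               tolerance = 0.05)
})

test_that("habitat contrasts recover simulated urban shifts and are zero for identical habitats", {
  d <- small_traits(seed = 31)
  fit <- fit_timing_model(d, "y_h", chains = 2, iter = 1500, warmup = 400,
                          seed = 7)
  hc <- habitat_contrasts(fit, "species")
  # simulated shifts: strong advances for blackbird/robin, near-zero
  # chaffinch; with 4 birds per species-habitat cell only the direction of
  # the early risers' pooled contrast is a stable target
  early <- mean(hc$median[hc$species %in% c("blackbird", "robin")])
  expect_lt(early, 0)
  expect_lt(abs(hc$median[hc$species == "chaffinch"]), 0.6)
  # a same-habitat contrast is exactly zero in every draw by construction
  des <- fit$design
  beta <- fit$draws[, colnames(des$X)]
  g <- data.frame(habitat = "urban", species = "robin",
                  season = "pre_breeding", year = "2020",
                  tmin_z = 0, precip_z = 0)
  for (f in names(des$xlev)) g[[f]] <- factor(g[[f]], levels = des$xlev[[f]])
  xrow <- model.matrix(des$formula, g)
  expect_true(all(drop(beta %*% t(xrow)) - drop(beta %*% t(xrow)) == 0))
  expect_error(habitat_contrasts(fit, "sex"))
})

test_that("sex models demand both sexes and recover a null sex-by-habitat interaction", {
  d <- small_traits(seed = 41)
  single <- d[d$sex %in% "M", ]
  expect_error(fit_timing_model(single, "y_h", sex_model = TRUE),
               "both sexes")
  fit <- fit_sex_timing_model(d, "y_h", chains = 2, iter = 800, warmup = 300,
                              seed = 5)
  ps <- posterior_summary(fit)
  sx <- ps[grepl("habitaturban:sexM|sexM:habitaturban", ps$parameter), ]
  expect_equal(nrow(sx), 1L)  # interaction present in the design
  expect_true(sx$q2.5 < 0 & sx$q97.5 > 0)  # simulated null: CrI spans zero
})

test_that("convergence diagnostics flag deliberately broken chains", {
  d <- small_traits(seed = 51)
  fit <- fit_timing_model(d, "y_h", chains = 2, iter = 800, warmup = 300,
                          seed = 2)
  expect_true(all(fit$diagnostics$table$rhat < 1.05, na.rm = TRUE))
  # two "chains" at different levels must be flagged
  broken <- fit
  broken$draws[broken$chain == 2, "sigma_B_urban"] <-
    broken$draws[broken$chain == 2, "sigma_B_urban"] + 5
  dg <- convergence_diagnostics(broken)
  expect_gt(dg$table$rhat[dg$table$parameter == "sigma_B_urban"], 1.5)
  expect_false(dg$pass)
  # single chain: limited diagnostics with a warning
  solo <- fit
  keep <- fit$chain == 1
  solo$draws <- fit$draws[keep, ]
  solo$chain <- fit$chain[keep]
  expect_warning(convergence_diagnostics(solo), "single chain")
})

test_that("the binomial activity model recovers habitat proportions and shrinks all-zero birds", {
  d <- simulate_activity_counts(n_birds_per_habitat = 15, n_days = 8,
                                sigma_b = list(urban = c(0.3, 0.3),
                                               forest = c(0.3, 0.3)),
                                sigma_w = list(urban = c(0.3, 0.3),
                                               forest = c(0.3, 0.3)),
                                seed = 6)
  noct <- d
  noct$n_active <- d$n_active_nocturnal
  noct$n_scored <- d$n_scored_nocturnal
  # an all-zero bird must not break the fit (shrinkage, no separation)
  noct$n_active[noct$bird_id == noct$bird_id[1]] <- 0L
  fit <- fit_activity_model(noct, chains = 2, iter = 800, warmup = 600,
                            seed = 3)
  mp <- fit$marginal_proportions
  expect_true(mp["urban", "median"] > 0.02 & mp["urban", "median"] < 0.09)
  expect_true(mp["forest", "median"] > 0.005 & mp["forest", "median"] < 0.04)
  expect_gt(mp["urban", "median"], mp["forest", "median"])
})
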