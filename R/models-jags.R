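# Binomial activity GLMMs and the bivariate diurnal-nocturnal model,
# sampled with JAGS. Residual (within-individual) variation enters through
# a habitat-specific observation-level random effect (OLRE) on the logit
# scale; the bivariate model correlates the bird-level and the OLRE effects
# across the two windows within each habitat.

JAGS_UNIVARIATE <- "
model {
  for (i in 1:N) {
    y[i] ~ dbin(p[i], m[i])
    logit(p[i]) <- inprod(X[i, ], beta) + u_site[site[i]] +
                   u_date[date[i]] + b[bird[i]] + o[i]
    o[i] ~ dnorm(0, tau_W[hab[i]])
  }
  for (j in 1:Nb) { b[j] ~ dnorm(0, tau_B[habb[j]]) }
  for (s in 1:Ns) { u_site[s] ~ dnorm(0, tau_site) }
  for (d in 1:Nd) { u_date[d] ~ dnorm(0, tau_date) }
  for (k in 1:P) { beta[k] ~ dnorm(0, 0.04) }
  for (h in 1:2) {
    sigma_B[h] ~ dt(0, 0.16, 3) T(0,)
    sigma_W[h] ~ dt(0, 0.16, 3) T(0,)
    tau_B[h] <- pow(sigma_B[h], -2)
    tau_W[h] <- pow(sigma_W[h], -2)
  }
  sigma_site ~ dt(0, 0.16, 3) T(0,)
  sigma_date ~ dt(0, 0.16, 3) T(0,)
  tau_site <- pow(sigma_site, -2)
  tau_date <- pow(sigma_date, -2)
}"

JAGS_BIVARIATE <- "
model {
  for (i in 1:N) {
    yd[i] ~ dbin(pd[i], md[i])
    yn[i] ~ dbin(pn[i], mn[i])
    logit(pd[i]) <- inprod(X[i, ], beta_d) + ud_site[site[i]] +
                    ud_date[date[i]] + b[bird[i], 1] + o[i, 1]
    logit(pn[i]) <- inprod(X[i, ], beta_n) + un_site[site[i]] +
                    un_date[date[i]] + b[bird[i], 2] + o[i, 2]
    o[i, 1:2] ~ dmnorm(zero2, Omega_W[hab[i], , ])
  }
  for (j in 1:Nb) { b[j, 1:2] ~ dmnorm(zero2, Omega_B[habb[j], , ]) }
  for (s in 1:Ns) {
    ud_site[s] ~ dnorm(0, tau_site[1])
    un_site[s] ~ dnorm(0, tau_site[2])
  }
  for (d in 1:Nd) {
    ud_date[d] ~ dnorm(0, tau_date[1])
    un_date[d] ~ dnorm(0, tau_date[2])
  }
  for (k in 1:P) {
    beta_d[k] ~ dnorm(0, 0.04)
    beta_n[k] ~ dnorm(0, 0.04)
  }
  for (h in 1:2) {
    for (r in 1:2) {
      sigma_B[h, r] ~ dt(0, 0.16, 3) T(0,)
      sigma_W[h, r] ~ dt(0, 0.16, 3) T(0,)
    }
    rho_B[h] ~ dunif(-0.98, 0.98)
    rho_W[h] ~ dunif(-0.98, 0.98)
    CovB[h, 1, 1] <- pow(sigma_B[h, 1], 2)
    CovB[h, 2, 2] <- pow(sigma_B[h, 2], 2)
    CovB[h, 1, 2] <- rho_B[h] * sigma_B[h, 1] * sigma_B[h, 2]
    CovB[h, 2, 1] <- CovB[h, 1, 2]
    Omega_B[h, 1:2, 1:2] <- inverse(CovB[h, , ])
    CovW[h, 1, 1] <- pow(sigma_W[h, 1], 2)
    CovW[h, 2, 2] <- pow(sigma_W[h, 2], 2)
    CovW[h, 1, 2] <- rho_W[h] * sigma_W[h, 1] * sigma_W[h, 2]
    CovW[h, 2, 1] <- CovW[h, 1, 2]
    Omega_W[h, 1:2, 1:2] <- inverse(CovW[h, , ])
  }
  for (r in 1:2) {
    sigma_site[r] ~ dt(0, 0.16, 3) T(0,)
    sigma_date[r] ~ dt(0, 0.16, 3) T(0,)
    tau_site[r] <- pow(sigma_site[r], -2)
    tau_date[r] <- pow(sigma_date[r], -2)
  }
}"

jags_to_fit <- function(samples, rename = identity) {
  mat_list <- lapply(samples, as.matrix)
  draws <- do.call(rbind, mat_list)
  colnames(draws) <- rename(colnames(draws))
  chain <- rep(seq_along(mat_list), vapply(mat_list, nrow, integer(1)))
  list(draws = draws, chain = chain)
}

prep_glmm_data <- function(data, need) {
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("data lacks required column(s): ", paste(missing, collapse = ", "))
  }
  data <- data[complete.cases(data[, need]), , drop = FALSE]
  birdf <- factor(data$bird_id)
  bird <- as.integer(birdf)
  habb <- hab_code(tapply(as.character(data$habitat), bird, `[`, 1)[
    as.character(seq_len(nlevels(birdf)))])
  list(data = data,
       des = build_fixed_design(data),
       site = as.integer(factor(data$site_id)),
       date = as.integer(factor(as.character(data$date))),
       bird = bird, habb = habb, hab = hab_code(data$habitat))
}

run_jags <- function(model_string, data_list, monitor, chains, iter,
                     warmup, seed, thin = 1L) {
  # the glm module provides block samplers that mix far better on
  # hierarchical binomial models than the base one-at-a-time samplers
  try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = substream_seed(seed, paste0("jags-chain-", ch)))
  })
  mod <- rjags::jags.model(textConnection(model_string), data = data_list,
                           inits = inits, n.chains = chains,
                           n.adapt = max(200L, warmup %/% 2L), quiet = TRUE)
  update(mod, warmup, progress.bar = "none")
  rjags::coda.samples(mod, monitor, n.iter = iter * thin, thin = thin,
                      progress.bar = "none")
}

#' Fit a binomial activity-level GLMM for one window
#'
#' Models active counts out of scored slots per bird-day with a logit link;
#' fixed and random structure as in [fit_timing_model()], plus a
#' habitat-specific observation-level random effect supplying the
#' within-individual variance component that a plain binomial model lacks.
#'
#' @param data bird-day table with `n_active`, `n_scored` plus the design
#'   columns of [fit_timing_model()].
#' @param chains,iter,warmup,thin MCMC controls (per-chain kept draws =
#'   `iter`).
#' @param seed integer seed.
#' @return a `diel_fit` with fixed effects and `sigma_site`, `sigma_date`,
#'   `sigma_B_*`, `sigma_W_*` (logit scale), plus derived per-habitat
#'   population activity proportions `prop_urban`, `prop_forest`
#'   (inverse-link marginal predictions averaged over the observed
#'   covariate rows of each habitat).
#' @export
fit_activity_model <- function(data, chains = 2L, iter = 2000L,
                               warmup = 1000L, thin = 1L, seed = 1L) {
  need <- c("habitat", "species", "season", "year", "tmin_c", "precip_mm",
            "site_id", "date", "bird_id", "n_active", "n_scored")
  pr <- prep_glmm_data(data, need)
  stopifnot(all(pr$data$n_active <= pr$data$n_scored))
  dl <- list(y = pr$data$n_active, m = pr$data$n_scored, X = pr$des$X,
             N = nrow(pr$data), P = ncol(pr$des$X),
             site = pr$site, date = pr$date, bird = pr$bird,
             hab = pr$hab, habb = pr$habb,
             Ns = max(pr$site), Nd = max(pr$date), Nb = max(pr$bird))
  samp <- run_jags(JAGS_UNIVARIATE, dl,
                   c("beta", "sigma_site", "sigma_date", "sigma_B", "sigma_W"),
                   chains, iter, warmup, seed, thin)
  res <- jags_to_fit(samp, function(nm) {
    nm <- sub("^beta\\[([0-9]+)\\]$", "B\\1", nm)
    for (j in seq_len(ncol(pr$des$X))) {
      nm[nm == paste0("B", j)] <- colnames(pr$des$X)[j]
    }
    nm <- sub("^sigma_B\\[1\\]$", "sigma_B_urban", nm)
    nm <- sub("^sigma_B\\[2\\]$", "sigma_B_forest", nm)
    nm <- sub("^sigma_W\\[1\\]$", "sigma_W_urban", nm)
    nm <- sub("^sigma_W\\[2\\]$", "sigma_W_forest", nm)
    nm
  })
  fit <- structure(list(
    kind = "binomial", response = "activity_level",
    draws = res$draws, chain = res$chain, chains = chains, iter = iter,
    warmup = warmup, design = pr$des, n_obs = nrow(pr$data),
    n_birds = c(urban = sum(pr$habb == 1L), forest = sum(pr$habb == 2L)),
    engine = "jags"
  ), class = "diel_fit")
  fit$diagnostics <- convergence_diagnostics(fit)
  fit$marginal_proportions <- marginal_proportions(fit, pr)
  fit
}

# Population-level activity proportion per habitat: inverse link of the
# fixed-effect linear predictor averaged over the observed covariate rows
# of that habitat, summarised over draws.
marginal_proportions <- function(fit, pr) {
  beta <- fit$draws[, colnames(pr$des$X), drop = FALSE]
  eta <- pr$des$X %*% t(beta)  # n x draws
  out <- lapply(c(urban = 1L, forest = 2L), function(h) {
    p <- colMeans(plogis(eta[pr$hab == h, , drop = FALSE]))
    c(median = median(p), quantile(p, c(0.025, 0.975)))
  })
  do.call(rbind, out)
}

#' Fit the bivariate diurnal-nocturnal activity model
#'
#' Joint binomial model of diurnal and nocturnal activity counts per
#' bird-day. Each response carries the shared fixed-effect structure and its
#' own site/date intercepts; bird-level effects and observation-level
#' effects are bivariate normal with habitat-specific SDs and correlations,
#' so the model estimates between-individual (`rho_B_*`) and
#' within-individual (`rho_W_*`) diurnal-nocturnal correlations per habitat
#' - the direct test of the day-night activity trade-off. Rows may carry
#' one response only (the other is treated as missing).
#'
#' @param data bird-day table with `n_active_diurnal`, `n_scored_diurnal`,
#'   `n_active_nocturnal`, `n_scored_nocturnal` plus the design columns.
#' @inheritParams fit_activity_model
#' @return a `diel_fit` with per-response SDs
#'   (`sigma_B_urban_diurnal`, ...), correlations `rho_B_urban`,
#'   `rho_W_forest`, ..., and per-draw cross-habitat correlation
#'   differences available via [variance_contrasts()]-style summaries.
#' @export
fit_bivariate_activity_model <- function(data, chains = 2L, iter = 2000L,
                                         warmup = 1000L, thin = 1L,
                                         seed = 1L) {
  need <- c("habitat", "species", "season", "year", "tmin_c", "precip_mm",
            "site_id", "date", "bird_id",
            "n_scored_diurnal", "n_scored_nocturnal")
  pr <- prep_glmm_data(data, need)
  d <- pr$data
  md <- pmax(d$n_scored_diurnal, 1L)
  mn <- pmax(d$n_scored_nocturnal, 1L)
  yd <- ifelse(d$n_scored_diurnal > 0, d$n_active_diurnal, NA)
  yn <- ifelse(d$n_scored_nocturnal > 0, d$n_active_nocturnal, NA)
  dl <- list(yd = yd, yn = yn, md = md, mn = mn, X = pr$des$X,
             N = nrow(d), P = ncol(pr$des$X),
             site = pr$site, date = pr$date, bird = pr$bird,
             hab = pr$hab, habb = pr$habb,
             Ns = max(pr$site), Nd = max(pr$date), Nb = max(pr$bird),
             zero2 = c(0, 0))
  samp <- run_jags(JAGS_BIVARIATE, dl,
                   c("beta_d", "beta_n", "sigma_site", "sigma_date",
                     "sigma_B", "sigma_W", "rho_B", "rho_W"),
                   chains, iter, warmup, seed, thin)
  habs <- c("urban", "forest")
  resp <- c("diurnal", "nocturnal")
  res <- jags_to_fit(samp, function(nm) {
    for (j in seq_len(ncol(pr$des$X))) {
      nm[nm == paste0("beta_d[", j, "]")] <-
        paste0(colnames(pr$des$X)[j], "_diurnal")
      nm[nm == paste0("beta_n[", j, "]")] <-
        paste0(colnames(pr$des$X)[j], "_nocturnal")
    }
    for (h in 1:2) {
      nm[nm == paste0("rho_B[", h, "]")] <- paste0("rho_B_", habs[h])
      nm[nm == paste0("rho_W[", h, "]")] <- paste0("rho_W_", habs[h])
      for (r in 1:2) {
        nm[nm == paste0("sigma_B[", h, ",", r, "]")] <-
          paste0("sigma_B_", habs[h], "_", resp[r])
        nm[nm == paste0("sigma_W[", h, ",", r, "]")] <-
          paste0("sigma_W_", habs[h], "_", resp[r])
      }
    }
    for (r in 1:2) {
      nm[nm == paste0("sigma_site[", r, "]")] <- paste0("sigma_site_", resp[r])
      nm[nm == paste0("sigma_date[", r, "]")] <- paste0("sigma_date_", resp[r])
    }
    nm
  })
  fit <- structure(list(
    kind = "bivariate", response = "diurnal+nocturnal",
    draws = res$draws, chain = res$chain, chains = chains, iter = iter,
    warmup = warmup, design = pr$des, n_obs = nrow(d),
    n_birds = c(urban = sum(pr$habb == 1L), forest = sum(pr$habb == 2L)),
    engine = "jags"
  ), class = "diel_fit")
  fit$diagnostics <- convergence_diagnostics(fit)
  fit
}

#' Cross-habitat differences of the bivariate correlations
#'
#' Urban minus forest difference, per draw, of the between-individual and
#' within-individual diurnal-nocturnal correlations.
#' @param fit a bivariate `diel_fit`.
#' @return data.frame as in [variance_contrasts()].
#' @export
correlation_contrasts <- function(fit) {
  stopifnot(fit$kind == "bivariate")
  summarise_contrasts(list(
    delta_rho_B = fit$draws[, "rho_B_urban"] - fit$draws[, "rho_B_forest"],
    delta_rho_W = fit$draws[, "rho_W_urban"] - fit$draws[, "rho_W_forest"]
  ))
}
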