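# User-facing hierarchical model fits and posterior derivations:
# habitat-specific variance components, repeatability, contrasts.

# Build the fixed-effects design shared by all models: habitat, species,
# season, year, standardized climate covariates, habitat x species and
# habitat x season. Terms whose factor has a single observed level are
# dropped automatically (e.g. one-season studies). Sex models add sex and
# its two-way interactions with habitat, season and species.
build_fixed_design <- function(data, sex_model = FALSE) {
  fac <- function(x, levels = NULL) {
    f <- factor(x, levels = levels %||% sort(unique(x)))
    droplevels(f)
  }
  df <- data.frame(
    habitat = fac(data$habitat, c("forest", "urban")),
    species = fac(data$species),
    season = fac(data$season),
    year = fac(data$year)
  )
  tmin_mu <- mean(data$tmin_c); tmin_sd <- sd(data$tmin_c)
  prec_mu <- mean(data$precip_mm); prec_sd <- sd(data$precip_mm)
  df$tmin_z <- if (isTRUE(tmin_sd > 0)) (data$tmin_c - tmin_mu) / tmin_sd else 0
  df$precip_z <- if (isTRUE(prec_sd > 0)) (data$precip_mm - prec_mu) / prec_sd else 0

  terms <- c("habitat")
  if (nlevels(df$species) > 1) terms <- c(terms, "species", "habitat:species")
  if (nlevels(df$season) > 1) terms <- c(terms, "season", "habitat:season")
  if (nlevels(df$year) > 1) terms <- c(terms, "year")
  if (isTRUE(tmin_sd > 0)) terms <- c(terms, "tmin_z")
  if (isTRUE(prec_sd > 0)) terms <- c(terms, "precip_z")
  if (sex_model) {
    df$sex <- fac(data$sex)
    if (nlevels(df$sex) < 2) {
      stop("sex model requires both sexes in the data; found only: ",
           paste(levels(df$sex), collapse = ", "))
    }
    terms <- c(terms, "sex", "sex:habitat")
    if (nlevels(df$season) > 1) terms <- c(terms, "sex:season")
    if (nlevels(df$species) > 1) terms <- c(terms, "sex:species")
  }
  fml <- stats::reformulate(terms)
  X <- model.matrix(fml, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed-effects design is rank deficient (aliased: ",
         paste(bad, collapse = ", "),
         "); check factor crossing in the data")
  }
  list(X = X, formula = fml, frame = df,
       scaling = list(tmin = c(tmin_mu, tmin_sd), precip = c(prec_mu, prec_sd)),
       xlev = lapply(Filter(is.factor, df), levels))
}

# Integer codes 1=urban, 2=forest.
hab_code <- function(h) ifelse(h == "urban", 1L, 2L)

#' Fit the heteroscedastic Bayesian timing model
#'
#' Linear mixed model for a relative-timing trait (onset, end or duration,
#' hours) with fixed effects habitat, species, season, year, standardized
#' daily minimum temperature and precipitation, habitat x species and
#' habitat x season; random intercepts for site and calendar date (crossed);
#' habitat-specific bird random-intercept SDs (between-individual variation)
#' and habitat-specific residual SDs (within-individual variation). Sampled
#' by a purpose-built conjugate Gibbs sampler; SD priors are half-t(3,
#' 2.5 sd(y)), fixed effects normal(0, 10 sd(y)).
#'
#' @param data bird-day table with columns `habitat`, `species`, `season`,
#'   `year`, `tmin_c`, `precip_mm`, `site_id`, `date`, `bird_id` and the
#'   response; incomplete rows are dropped.
#' @param response name of the response column (e.g. `"relative_onset_h"`).
#' @param chains,iter,warmup MCMC size (post-warmup `iter` per chain).
#' @param seed integer seed.
#' @param sex_model include sex and its interactions (restricts the data to
#'   rows with known sex).
#' @return object of class `diel_fit` with posterior `draws` (fixed effects
#'   and `sigma_site`, `sigma_date`, `sigma_B_urban`, `sigma_B_forest`,
#'   `sigma_W_urban`, `sigma_W_forest`), chain ids, design metadata and
#'   convergence diagnostics.
#' @export
fit_timing_model <- function(data, response = "relative_onset_h",
                             chains = 4L, iter = 2000L, warmup = 500L,
                             seed = 1L, sex_model = FALSE) {
  need <- c("habitat", "species", "season", "year", "tmin_c", "precip_mm",
            "site_id", "date", "bird_id", response)
  if (sex_model) need <- c(need, "sex")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("data lacks required column(s): ", paste(missing, collapse = ", "))
  }
  data <- data[complete.cases(data[, need]), , drop = FALSE]
  if (sex_model) data <- data[data$species %in% SEXABLE_SPECIES, , drop = FALSE]
  y <- data[[response]]
  if (length(unique(data$bird_id[data$habitat == "urban"])) < 2 ||
      length(unique(data$bird_id[data$habitat == "forest"])) < 2) {
    stop("need at least 2 birds per habitat to separate between- and ",
         "within-individual variance")
  }
  des <- build_fixed_design(data, sex_model = sex_model)
  site <- as.integer(factor(data$site_id))
  date <- as.integer(factor(as.character(data$date)))
  birdf <- factor(data$bird_id)
  bird <- as.integer(birdf)
  hab_obs <- hab_code(data$habitat)
  hab_bird <- hab_code(tapply(as.character(data$habitat), bird, `[`, 1)[
    as.character(seq_len(nlevels(birdf)))])

  res <- gibbs_hetero_lmm(y, des$X, site, date, bird, hab_obs, hab_bird,
                          chains = chains, iter = iter, warmup = warmup,
                          seed = seed)
  fit <- structure(list(
    kind = if (sex_model) "timing_sex" else "timing",
    response = response,
    draws = res$draws, chain = res$chain,
    chains = chains, iter = iter, warmup = warmup,
    design = des, priors = res$priors,
    n_obs = length(y),
    n_birds = c(urban = sum(hab_bird == 1L), forest = sum(hab_bird == 2L)),
    engine = "gibbs"
  ), class = "diel_fit")
  fit$diagnostics <- convergence_diagnostics(fit)
  fit
}

#' @rdname fit_timing_model
#' @export
fit_sex_timing_model <- function(data, response = "relative_onset_h", ...) {
  fit_timing_model(data, response, sex_model = TRUE, ...)
}

#' Posterior summary table of a fitted model
#'
#' @param fit a `diel_fit`.
#' @param pars optional parameter subset.
#' @return data.frame with parameter, posterior median, 95% credible
#'   interval bounds, R-hat and effective sample size.
#' @export
posterior_summary <- function(fit, pars = NULL) {
  d <- fit$draws
  if (!is.null(pars)) d <- d[, pars, drop = FALSE]
  qs <- t(apply(d, 2, quantile, c(0.5, 0.025, 0.975)))
  diag <- fit$diagnostics$table
  out <- data.frame(parameter = colnames(d),
                    median = qs[, 1], q2.5 = qs[, 2], q97.5 = qs[, 3],
                    rhat = diag$rhat[match(colnames(d), diag$parameter)],
                    ess = diag$ess[match(colnames(d), diag$parameter)],
                    row.names = NULL)
  out
}

#' @export
print.diel_fit <- function(x, ...) {
  cat("dielscope", x$kind, "model fit (", x$engine, "), response:",
      x$response %||% "", "\n")
  cat(x$n_obs, "observations;", x$chains, "chains x", x$iter, "draws\n")
  cat("max R-hat:", round(max(x$diagnostics$table$rhat, na.rm = TRUE), 4),
      if (x$diagnostics$pass) "(converged)" else "(NOT converged)", "\n")
  sd_pars <- grep("^(sigma|rho)", colnames(x$draws), value = TRUE)
  print(posterior_summary(x, sd_pars), digits = 3)
  invisible(x)
}

#' MCMC convergence diagnostics
#'
#' Split-chain R-hat (each chain halved, so 2x`chains` sequences) and
#' effective sample size per parameter; the fit passes when every R-hat is
#' below 1.01.
#'
#' @param fit a `diel_fit`.
#' @return list: `table` (parameter, rhat, ess), `pass`, `n_chains`.
#' @export
convergence_diagnostics <- function(fit) {
  d <- fit$draws
  ch <- fit$chain
  if (length(unique(ch)) < 2L) {
    warning("single chain: R-hat requires >= 2 chains; reporting split-",
            "half R-hat within the chain only")
  }
  rhat <- vapply(seq_len(ncol(d)), function(j) split_rhat(d[, j], ch),
                 numeric(1))
  ess <- vapply(seq_len(ncol(d)), function(j) {
    ml <- coda::mcmc.list(lapply(split(d[, j], ch), coda::mcmc))
    sum(coda::effectiveSize(ml))
  }, numeric(1))
  tab <- data.frame(parameter = colnames(d), rhat = rhat, ess = ess)
  list(table = tab, pass = all(is.finite(tab$rhat) & tab$rhat < 1.01),
       n_chains = length(unique(ch)))
}

# Split R-hat of one parameter: each chain is halved before the classic
# Gelman-Rubin between/within comparison.
split_rhat <- function(x, chain) {
  seqs <- unlist(lapply(split(x, chain), function(v) {
    m <- floor(length(v) / 2)
    list(v[seq_len(m)], v[m + seq_len(m)])
  }), recursive = FALSE)
  m <- length(seqs)
  n <- length(seqs[[1]])
  means <- vapply(seqs, mean, numeric(1))
  vars <- vapply(seqs, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Habitat-specific repeatability from a fitted model
#'
#' Per posterior draw, `R_h = sigma_B_h^2 / (sigma_B_h^2 + sigma_W_h^2)`:
#' the proportion of (bird-level plus residual) phenotypic variance
#' attributable to differences among individuals. Site and date variance is
#' excluded from the denominator. For binomial fits the within-individual
#' component is the observation-level random-effect SD on the link scale.
#'
#' @param fit a `diel_fit`.
#' @param habitat `"urban"` or `"forest"`.
#' @param response for bivariate fits, which response margin.
#' @return list: `draws`, `median`, `ci` (95% CrI).
#' @export
repeatability <- function(fit, habitat = c("urban", "forest"),
                          response = NULL) {
  habitat <- match.arg(habitat)
  suff <- if (!is.null(response)) paste0("_", response) else ""
  sB <- fit$draws[, paste0("sigma_B_", habitat, suff)]
  sW <- fit$draws[, paste0("sigma_W_", habitat, suff)]
  r <- sB^2 / (sB^2 + sW^2)
  list(draws = r, median = median(r),
       ci = unname(quantile(r, c(0.025, 0.975))))
}

#' Urban minus forest differences in variance components and repeatability
#'
#' Per-draw contrasts of the between-individual SD, within-individual SD
#' and repeatability across habitats, with medians, 95% CrIs and the
#' evidence flag (CrI excludes zero).
#'
#' @param fit a `diel_fit`.
#' @param response for bivariate fits, which response margin.
#' @return data.frame with one row per quantity
#'   (`delta_sigma_B`, `delta_sigma_W`, `delta_R`).
#' @export
variance_contrasts <- function(fit, response = NULL) {
  suff <- if (!is.null(response)) paste0("_", response) else ""
  dB <- fit$draws[, paste0("sigma_B_urban", suff)] -
    fit$draws[, paste0("sigma_B_forest", suff)]
  dW <- fit$draws[, paste0("sigma_W_urban", suff)] -
    fit$draws[, paste0("sigma_W_forest", suff)]
  dR <- repeatability(fit, "urban", response)$draws -
    repeatability(fit, "forest", response)$draws
  summarise_contrasts(list(delta_sigma_B = dB, delta_sigma_W = dW,
                           delta_R = dR))
}

summarise_contrasts <- function(lst) {
  out <- do.call(rbind, lapply(names(lst), function(nm) {
    x <- lst[[nm]]
    q <- quantile(x, c(0.025, 0.975))
    data.frame(contrast = nm, median = median(x),
               q2.5 = q[1], q97.5 = q[2],
               evidence = unname(q[1] > 0 | q[2] < 0))
  }))
  rownames(out) <- NULL
  out
}

#' Urban minus forest marginal contrasts by species or season
#'
#' Builds, per posterior draw, the difference in the linear predictor
#' between an urban and a forest bird of each species (averaged over the
#' observed seasons and years, covariates at their means) or of each season
#' (averaged over species and years).
#'
#' @param fit a `diel_fit` (timing or binomial; contrasts are on the
#'   response scale for timing fits and the logit scale for binomial fits).
#' @param by `"species"` or `"season"`.
#' @return data.frame: level, median difference, 95% CrI, evidence flag.
#' @export
habitat_contrasts <- function(fit, by = c("species", "season")) {
  by <- match.arg(by)
  des <- fit$design
  xl <- des$xlev
  if (!by %in% names(xl)) {
    stop("model has no '", by, "' factor with multiple levels")
  }
  beta_cols <- colnames(des$X)
  draws <- fit$draws[, beta_cols, drop = FALSE]
  avg_levels <- function(nm) xl[[nm]] %||% NA
  lv <- xl[[by]]
  out <- lapply(lv, function(l) {
    grid <- expand.grid(
      species = if (by == "species") l else avg_levels("species"),
      season = if (by == "season") l else avg_levels("season"),
      year = avg_levels("year"),
      sex = if ("sex" %in% names(xl)) xl$sex else NA,
      stringsAsFactors = FALSE
    )
    grid <- grid[, !vapply(grid, function(c) all(is.na(c)), logical(1)),
                 drop = FALSE]
    rowvec <- function(hab) {
      g <- grid
      g$habitat <- hab
      g$tmin_z <- 0
      g$precip_z <- 0
      for (f in names(xl)) g[[f]] <- factor(g[[f]], levels = xl[[f]])
      X <- model.matrix(des$formula, g)
      colMeans(X[, beta_cols, drop = FALSE])
    }
    cvec <- rowvec("urban") - rowvec("forest")
    drop(draws %*% cvec)
  })
  names(out) <- lv
  res <- summarise_contrasts(out)
  names(res)[1] <- by
  res
}
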