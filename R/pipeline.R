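# End-to-end orchestration: simulate -> preprocess -> windows -> detect ->
# levels -> fit -> report, with a manifest reconciling row counts across
# stages.

#' Run the full diel-activity pipeline on a synthetic study
#'
#' Executes every stage in order, writes all intermediate tables as CSV
#' into `out_dir` (when given) and returns the result bundle with a
#' manifest. The manifest records the config hash, seed, and per-stage
#' input/output/filter counts, which reconcile exactly:
#' raw windows = estimates + coverage-filtered + too-short.
#'
#' @param config a [sim_config()] (or path to its YAML).
#' @param out_dir optional output directory for CSV artifacts.
#' @param fit_models character subset of
#'   `c("onset", "end", "duration", "diurnal", "nocturnal", "bivariate")`;
#'   hierarchical models to fit (the timing trio via the Gibbs sampler, the
#'   activity models via JAGS).
#' @param chains,iter,warmup MCMC controls passed to the fitters.
#' @param method transition estimation method.
#' @return list of class `diel_run`: `study`, `estimates`, `levels`,
#'   `fits`, `report`, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         fit_models = c("onset"),
                         chains = 4L, iter = 2000L, warmup = 500L,
                         method = "changepoint") {
  if (is.character(config)) config <- read_sim_config(config)
  validate_sim_config(config)
  t0 <- Sys.time()

  study <- simulate_study(config)
  est <- estimate_activity(study$detections, study$birds, study$solar,
                           method = method)
  lev <- activity_levels(study$detections, study$birds, study$solar)

  model_data <- merge_model_data(est$estimates, study)
  level_data <- merge_level_data(lev$levels, study)

  fits <- list()
  resp_map <- c(onset = "relative_onset_h", end = "relative_end_h",
                duration = "duration_h")
  for (m in intersect(fit_models, names(resp_map))) {
    fits[[m]] <- fit_timing_model(model_data, resp_map[[m]],
                                  chains = chains, iter = iter,
                                  warmup = warmup, seed = config$seed)
  }
  for (m in intersect(fit_models, c("diurnal", "nocturnal"))) {
    dat <- level_data[level_data$window == m, ]
    fits[[m]] <- fit_activity_model(dat, chains = min(chains, 2L),
                                    iter = iter, warmup = max(warmup, 1000L),
                                    seed = config$seed)
  }
  if ("bivariate" %in% fit_models) {
    fits$bivariate <- fit_bivariate_activity_model(
      widen_levels(level_data), chains = min(chains, 2L), iter = iter,
      warmup = max(warmup, 1000L), seed = config$seed)
  }

  report <- build_report(est$estimates, lev$levels, study, fits)
  manifest <- list(
    config_hash = content_hash(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("dielscope")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    counts = list(
      detections = nrow(study$detections),
      birds = nrow(study$birds),
      timing = est$accounting,
      levels = lev$accounting
    )
  )
  out <- list(study = study, estimates = est$estimates,
              accounting = est$accounting, levels = lev$levels,
              fits = fits, report = report, manifest = manifest)
  class(out) <- "diel_run"
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

merge_model_data <- function(estimates, study) {
  md <- merge(estimates, study$birds[, c("bird_id", "species", "habitat", "sex")],
              by = "bird_id")
  md <- merge(md, study$climate, by = c("site_id", "date"))
  md$season <- study$config$season
  md$year <- study$config$year
  md
}

merge_level_data <- function(levels, study) {
  ld <- merge(levels, study$birds[, c("bird_id", "species", "habitat", "sex")],
              by = "bird_id")
  ld <- merge(ld, study$climate, by = c("site_id", "date"))
  ld$season <- study$config$season
  ld$year <- study$config$year
  ld
}

# long (window column) -> wide bird-day table for the bivariate model
widen_levels <- function(level_data) {
  keys <- c("bird_id", "site_id", "date", "species", "habitat", "sex",
            "season", "year", "tmin_c", "precip_mm")
  d <- level_data[level_data$window == "diurnal", c(keys, "n_active", "n_scored")]
  names(d)[names(d) %in% c("n_active", "n_scored")] <-
    c("n_active_diurnal", "n_scored_diurnal")
  n <- level_data[level_data$window == "nocturnal", c(keys, "n_active", "n_scored")]
  names(n)[names(n) %in% c("n_active", "n_scored")] <-
    c("n_active_nocturnal", "n_scored_nocturnal")
  out <- merge(d, n, by = keys, all = TRUE)
  out$n_scored_diurnal[is.na(out$n_scored_diurnal)] <- 0L
  out$n_scored_nocturnal[is.na(out$n_scored_nocturnal)] <- 0L
  out
}

build_report <- function(estimates, levels, study, fits) {
  est <- merge(estimates, study$birds[, c("bird_id", "habitat")], by = "bird_id")
  lv <- merge(levels, study$birds[, c("bird_id", "habitat")], by = "bird_id")
  by_hab <- function(x, hab, f, ...) f(x[est$habitat == hab], ...)
  desc <- do.call(rbind, lapply(c("urban", "forest"), function(h) {
    data.frame(
      habitat = h,
      mean_relative_onset_h = mean(est$relative_onset_h[est$habitat == h],
                                   na.rm = TRUE),
      sd_relative_onset_h = sd(est$relative_onset_h[est$habitat == h],
                               na.rm = TRUE),
      mean_relative_end_h = mean(est$relative_end_h[est$habitat == h],
                                 na.rm = TRUE),
      sd_relative_end_h = sd(est$relative_end_h[est$habitat == h],
                             na.rm = TRUE),
      mean_duration_h = mean(est$duration_h[est$habitat == h], na.rm = TRUE),
      diurnal_proportion = pooled_proportion(
        lv[lv$habitat == h & lv$window == "diurnal", ]),
      nocturnal_proportion = pooled_proportion(
        lv[lv$habitat == h & lv$window == "nocturnal", ])
    )
  }))
  rep <- list(descriptives = desc)
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (f$kind %in% c("timing", "timing_sex")) {
      rep[[paste0(nm, "_variance_contrasts")]] <- variance_contrasts(f)
      rep[[paste0(nm, "_species_contrasts")]] <-
        tryCatch(habitat_contrasts(f, "species"), error = function(e) NULL)
      rep[[paste0(nm, "_repeatability")]] <- data.frame(
        habitat = c("urban", "forest"),
        median = c(repeatability(f, "urban")$median,
                   repeatability(f, "forest")$median),
        q2.5 = c(repeatability(f, "urban")$ci[1],
                 repeatability(f, "forest")$ci[1]),
        q97.5 = c(repeatability(f, "urban")$ci[2],
                  repeatability(f, "forest")$ci[2])
      )
    }
    if (f$kind == "binomial") {
      rep[[paste0(nm, "_marginal_proportions")]] <- f$marginal_proportions
    }
    if (f$kind == "bivariate") {
      rep$bivariate_correlations <- posterior_summary(
        f, grep("^rho", colnames(f$draws), value = TRUE))
      rep$bivariate_correlation_contrasts <- correlation_contrasts(f)
    }
  }
  rep
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_study(run$study, file.path(out_dir, "study"))
  write.csv(run$estimates, file.path(out_dir, "activity_estimates.csv"),
            row.names = FALSE)
  write.csv(run$levels, file.path(out_dir, "activity_levels.csv"),
            row.names = FALSE)
  for (nm in names(run$fits)) {
    write.csv(posterior_summary(run$fits[[nm]]),
              file.path(out_dir, paste0("posterior_summary_", nm, ".csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.diel_run <- function(x, ...) {
  cat("dielscope pipeline run", x$manifest$config_hash, "\n")
  cat("detections:", x$manifest$counts$detections,
      " birds:", x$manifest$counts$birds, "\n")
  print(x$accounting)
  cat("\nDescriptives by habitat:\n")
  print(x$report$descriptives, digits = 3)
  invisible(x)
}
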