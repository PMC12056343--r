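# Synthetic telemetry generator: per-bird diel square-wave schedules with
# known ground truth, turned into per-receiver signal-strength detections.
#
# Reproducibility contract: every random draw happens inside a named RNG
# substream keyed by (purpose, bird [, receiver | date]), derived from the
# master seed. Adding birds, days or receivers to a config never changes
# the draws of existing units.

#' Simulate a full synthetic telemetry study
#'
#' Generates the complete raw-data bundle downstream stages consume:
#' per-receiver detection records, bird and site metadata, daily climate
#' covariates, per-site-date solar times, and a ground-truth table holding
#' each bird's latent timing deviations and each day's true onset/end.
#'
#' Each bird carries one between-individual deviation for onset and one for
#' end (SD set per habitat); each bird-day adds an independent
#' within-individual deviation. True onset is sunrise + species baseline +
#' urban shift (urban birds only) + bird deviation + day deviation; true end
#' is the same construction around sunset. Within `[onset, end)` the bird is
#' active in each 3-min slot with the habitat's diurnal probability (daytime
#' rest gaps); in the 22:00-02:00 nocturnal window it is active with the
#' habitat's nocturnal probability. Movement in an active slot displaces the
#' bird, so each receiver's latent signal level jumps by at least
#' `signal_step_active_dB`; while static the level holds and only receiver
#' noise remains. Each slot is independently detected with probability
#' `detection_prob` per receiver.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `diel_study`: list with `detections`,
#'   `birds`, `sites`, `climate`, `solar`, `truth` data.frames and the
#'   `config`.
#' @export
simulate_study <- function(config) {
  validate_sim_config(config)
  cfg <- config
  sites <- default_sites(cfg$sites_per_habitat)
  tz <- sites$tz[1]
  dates <- season_start_date(cfg$season, cfg$year) + seq_len(cfg$n_days) - 1L

  birds <- build_birds(cfg, sites)
  solar <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    cbind(site_id = sites$site_id[i],
          solar_times(sites$lat[i], sites$lon[i], dates, tz))
  }))

  # between-individual deviations: one pair per bird, keyed by bird only
  birds$onset_between_dev_h <- vapply(seq_len(nrow(birds)), function(i) {
    with_substream(cfg$seed, paste0("between/", birds$bird_id[i]),
                   rnorm(1, 0, cfg$between_sd_onset_h[birds$habitat[i]]))
  }, numeric(1))
  birds$end_between_dev_h <- vapply(seq_len(nrow(birds)), function(i) {
    with_substream(cfg$seed, paste0("between-end/", birds$bird_id[i]),
                   rnorm(1, 0, cfg$between_sd_end_h[birds$habitat[i]]))
  }, numeric(1))

  # receiver baselines: one per bird-receiver pair
  rec_ids <- function(site) paste0(site, "_r", seq_len(cfg$n_receivers_per_site))

  det_list <- vector("list", nrow(birds))
  truth_list <- vector("list", nrow(birds))
  for (i in seq_len(nrow(birds))) {
    bird <- birds[i, ]
    receivers <- data.frame(
      receiver_id = rec_ids(bird$site_id),
      baseline_dB = vapply(seq_len(cfg$n_receivers_per_site), function(r) {
        with_substream(cfg$seed,
                       paste0("baseline/", bird$bird_id, "/r", r),
                       runif(1, -120, -60))
      }, numeric(1))
    )
    sol_b <- solar[solar$site_id == bird$site_id, ]
    level <- rep(0, nrow(receivers))  # latent position offset per receiver
    day_det <- vector("list", length(dates))
    day_truth <- vector("list", length(dates))
    for (d in seq_along(dates)) {
      sched <- simulate_bird_day(bird, dates[d],
                                 sol_b[sol_b$date == dates[d], ], cfg, tz)
      sig <- schedule_to_signal(sched, receivers, cfg, level_init = level)
      level <- sig$level_final
      day_det[[d]] <- sig$detections
      day_truth[[d]] <- data.frame(
        bird_id = bird$bird_id, site_id = bird$site_id,
        habitat = bird$habitat, species = bird$species, date = dates[d],
        true_onset = sched$true_onset, true_end = sched$true_end,
        onset_between_dev_h = bird$onset_between_dev_h,
        end_between_dev_h = bird$end_between_dev_h,
        onset_day_dev_h = sched$onset_day_dev_h,
        end_day_dev_h = sched$end_day_dev_h,
        n_active_slots = sum(sched$active),
        n_nocturnal_active = sched$n_nocturnal_active
      )
    }
    det_list[[i]] <- rbindlist(day_det)
    truth_list[[i]] <- rbindlist(day_truth)
  }
  detections <- setDF(rbindlist(det_list))
  detections <- detections[order(detections$tag_id, detections$receiver_id,
                                 detections$timestamp), ]
  rownames(detections) <- NULL

  climate <- simulate_climate(sites, dates, cfg)

  out <- list(detections = detections, birds = birds, sites = sites,
              climate = climate, solar = solar,
              truth = setDF(rbindlist(truth_list)), config = cfg)
  class(out) <- "diel_study"
  out
}

build_birds <- function(cfg, sites) {
  rows <- list()
  for (hab in cfg$habitats) {
    hs <- sites$site_id[sites$habitat == hab]
    k <- 0L
    for (sp in cfg$species_list) {
      for (j in seq_len(cfg$n_birds_per_species_per_habitat)) {
        k <- k + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          bird_id = sprintf("%s_%s_%02d", substr(hab, 1, 1), sp, j),
          species = sp, habitat = hab,
          site_id = hs[(k - 1L) %% length(hs) + 1L],
          sex = if (sp %in% SEXABLE_SPECIES) {
            if (j %% 2L == 1L) "M" else "F"
          } else NA_character_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out$tag_id <- out$bird_id
  out
}

#' Simulate one bird-day schedule (ground truth)
#'
#' Draws the day's true onset and end around sunrise/sunset and the per-slot
#' activity mask on the 3-min grid anchored at local midnight.
#'
#' @param bird one row of the bird table (needs `bird_id`, `species`,
#'   `habitat`, `site_id`, `onset_between_dev_h`, `end_between_dev_h`).
#' @param date the simulated `Date`.
#' @param solar_day the matching row of the solar table.
#' @param config a [sim_config()].
#' @param tz site timezone.
#' @return a list: `true_onset`, `true_end` (POSIXct), day deviations (h),
#'   `slots` (global 3-min slot indices of the day), `active` logical mask,
#'   `n_nocturnal_active`.
#' @export
simulate_bird_day <- function(bird, date, solar_day, config, tz = "Europe/London") {
  cfg <- config
  hab <- bird$habitat
  sp <- bird$species
  shift_on <- cfg$species_onset_h[[sp]] +
    if (hab == "urban") cfg$mean_onset_shift_urban_h[[sp]] else 0
  shift_end <- cfg$species_end_h[[sp]] +
    if (hab == "urban") cfg$mean_end_shift_urban_h[[sp]] else 0

  key <- paste0("day/", bird$site_id, "/", bird$bird_id, "/", format(date))
  with_substream(cfg$seed, key, {
    onset_day_dev <- rnorm(1, 0, cfg$within_sd_onset_h[[hab]])
    end_day_dev <- rnorm(1, 0, cfg$within_sd_end_h[[hab]])
    true_onset <- solar_day$sunrise +
      3600 * (shift_on + bird$onset_between_dev_h + onset_day_dev)
    true_end <- solar_day$sunset +
      3600 * (shift_end + bird$end_between_dev_h + end_day_dev)
    if (true_end <= true_onset) {  # degenerate draw: enforce a minimal day
      true_end <- true_onset + 3600
    }

    mid <- local_midnight(date, tz)
    slot0 <- time_to_slot(mid)
    slots <- slot0 + seq_len(SLOTS_PER_DAY) - 1L
    slot_start <- as.numeric(mid) + (seq_len(SLOTS_PER_DAY) - 1L) * 180

    in_day <- slot_start >= as.numeric(true_onset) &
      slot_start < as.numeric(true_end)
    active <- in_day & runif(SLOTS_PER_DAY) < cfg$diurnal_active_prob[[hab]]

    # nocturnal bouts: local clock 22:00-24:00 and 00:00-02:00, outside the
    # active phase (both halves of the window are covered across days)
    hour <- (slot_start - as.numeric(mid)) / 3600
    noct_elig <- (hour >= 22 | hour < 2) & !in_day
    noct <- noct_elig & runif(SLOTS_PER_DAY) < cfg$nocturnal_active_prob[[hab]]
    active <- active | noct

    list(bird_id = bird$bird_id, date = date,
         true_onset = true_onset, true_end = true_end,
         onset_day_dev_h = onset_day_dev, end_day_dev_h = end_day_dev,
         slots = slots, slot_start = slot_start, active = active,
         n_nocturnal_active = sum(noct))
  })
}

#' Turn a day schedule into per-receiver detection records
#'
#' Implements the movement-to-signal premise of the telemetry system: a
#' static bird gives a constant received level plus noise; movement in an
#' active slot relocates the bird so each receiver's latent level jumps by a
#' uniform magnitude in `[step, 2 step]` dB with random sign (reflected
#' towards the baseline beyond +/- 40 dB so levels stay in a physical
#' range). The latent level persists across slots (and days, via
#' `level_init`), so the signal differential exceeds the step only in
#' active slots.
#'
#' @param schedule a [simulate_bird_day()] result.
#' @param receivers data.frame with `receiver_id`, `baseline_dB`.
#' @param config a [sim_config()].
#' @param level_init numeric vector, latent level offset per receiver at the
#'   start of the day (default all 0).
#' @param tz site timezone used to render timestamps.
#' @return list with `detections` (tag_id, receiver_id, timestamp,
#'   signal_dB) and `level_final` (per-receiver latent level carry-over).
#' @export
schedule_to_signal <- function(schedule, receivers, config,
                               level_init = NULL, tz = "Europe/London") {
  cfg <- config
  nr <- nrow(receivers)
  ns <- length(schedule$slots)
  if (is.null(level_init)) level_init <- rep(0, nr)
  key <- paste0("signal/", schedule$bird_id, "/", format(schedule$date))
  with_substream(cfg$seed, key, {
    act <- schedule$active
    idx_act <- which(act)
    out <- vector("list", nr)
    level_final <- numeric(nr)
    for (r in seq_len(nr)) {
      level <- numeric(ns)
      cur <- level_init[r]
      if (length(idx_act)) {
        mag <- runif(length(idx_act), cfg$signal_step_active_dB,
                     2 * cfg$signal_step_active_dB)
        sgn <- sample(c(-1, 1), length(idx_act), replace = TRUE)
      }
      ai <- 0L
      for (t in seq_len(ns)) {
        if (act[t]) {
          ai <- ai + 1L
          s <- sgn[ai]
          if (abs(cur) > 40) s <- -sign(cur)
          cur <- cur + s * mag[ai]
        }
        level[t] <- cur
      }
      level_final[r] <- cur
      sig <- receivers$baseline_dB[r] + level +
        rnorm(ns, 0, cfg$signal_noise_inactive_dB)
      keep <- runif(ns) < cfg$detection_prob
      out[[r]] <- data.frame(
        tag_id = schedule$bird_id,
        receiver_id = receivers$receiver_id[r],
        timestamp = as.POSIXct(schedule$slot_start[keep],
                               origin = "1970-01-01", tz = tz),
        signal_dB = round(sig[keep], 2)
      )
    }
    list(detections = setDF(rbindlist(out)), level_final = level_final)
  })
}

simulate_climate <- function(sites, dates, cfg) {
  seasonal_tmin <- if (cfg$season == "pre_breeding") 2.5 else 7.0
  out <- lapply(sites$site_id, function(s) {
    with_substream(cfg$seed, paste0("climate/", s), {
      n <- length(dates)
      ar1 <- function(mu, phi, sd) {
        x <- numeric(n)
        x[1] <- rnorm(1, mu, sd / sqrt(1 - phi^2))
        for (t in seq_len(n - 1)) {
          x[t + 1] <- mu + phi * (x[t] - mu) + rnorm(1, 0, sd)
        }
        x
      }
      data.frame(site_id = s, date = dates,
                 tmin_c = round(ar1(seasonal_tmin, 0.7, 1.8), 2),
                 precip_mm = round(pmax(0, ar1(1.5, 0.4, 2.5)), 2))
    })
  })
  do.call(rbind, out)
}

#' Write a synthetic study to CSV files
#'
#' Emits `detections.csv`, `birds.csv`, `sites.csv`, `climate.csv`,
#' `solar.csv` and `truth.csv` into `dir`. Timestamps are ISO-8601 with
#' numeric UTC offset.
#'
#' @param study a `diel_study` from [simulate_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) format(x, "%Y-%m-%dT%H:%M:%S%z")
  det <- study$detections
  det$timestamp <- fmt(det$timestamp)
  write.csv(det, file.path(dir, "detections.csv"), row.names = FALSE)
  write.csv(study$birds, file.path(dir, "birds.csv"), row.names = FALSE)
  write.csv(study$sites, file.path(dir, "sites.csv"), row.names = FALSE)
  write.csv(study$climate, file.path(dir, "climate.csv"), row.names = FALSE)
  sol <- study$solar
  sol$sunrise <- fmt(sol$sunrise)
  sol$sunset <- fmt(sol$sunset)
  write.csv(sol, file.path(dir, "solar.csv"), row.names = FALSE)
  tr <- study$truth
  tr$true_onset <- fmt(tr$true_onset)
  tr$true_end <- fmt(tr$true_end)
  write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Simulate timing traits directly from the hierarchical trait model
#'
#' Draws a bird-day table of a relative-timing response (e.g. onset relative
#' to sunrise, hours) straight from the generative trait model, bypassing
#' the signal layer. Intended for parameter-recovery and calibration studies
#' of the hierarchical models, where the signal-processing chain would only
#' add runtime, not information.
#'
#' @param n_birds_per_habitat birds per habitat (split over species/sites).
#' @param n_days days per bird.
#' @param config a [sim_config()]; timing means/SDs are taken from it.
#' @param response `"onset"` or `"end"`.
#' @param sigma_site,sigma_date SDs of the site and date random intercepts.
#' @param beta_tmin,beta_precip effects (h per SD) of the standardized
#'   climate covariates.
#' @param seed integer seed.
#' @return data.frame with bird_id, species, habitat, site_id, sex, date,
#'   season, year, tmin_c, precip_mm, response column `y_h`, and the true
#'   per-bird deviation `between_dev_h`.
#' @export
simulate_timing_traits <- function(n_birds_per_habitat = 75L,
                                   n_days = 20L,
                                   config = sim_config(),
                                   response = c("onset", "end"),
                                   sigma_site = 0.05,
                                   sigma_date = 0.05,
                                   beta_tmin = 0,
                                   beta_precip = 0,
                                   seed = 1L) {
  response <- match.arg(response)
  cfg <- config
  set.seed(seed)
  sites <- default_sites(cfg$sites_per_habitat)
  dates <- season_start_date(cfg$season, cfg$year) + seq_len(n_days) - 1L
  between_sd <- cfg[[paste0("between_sd_", response, "_h")]]
  within_sd <- cfg[[paste0("within_sd_", response, "_h")]]
  sp_base <- cfg[[paste0("species_", response, "_h")]]
  urb_shift <- cfg[[paste0("mean_", response, "_shift_urban_h")]]

  rows <- list()
  u_date <- rnorm(n_days, 0, sigma_date)
  u_site <- rnorm(nrow(sites), 0, sigma_site)
  names(u_site) <- sites$site_id
  climate <- simulate_climate(sites, dates, cfg)
  tmin_z <- scale(climate$tmin_c)[, 1]
  precip_z <- scale(climate$precip_mm)[, 1]
  climate$tmin_z <- tmin_z
  climate$precip_z <- precip_z

  for (hab in cfg$habitats) {
    hs <- sites$site_id[sites$habitat == hab]
    for (j in seq_len(n_birds_per_habitat)) {
      sp <- cfg$species_list[(j - 1L) %% length(cfg$species_list) + 1L]
      # balance species across sites: rotate site blocks per species cycle
      site <- hs[((j - 1L) %/% length(cfg$species_list)) %% length(hs) + 1L]
      bdev <- rnorm(1, 0, between_sd[[hab]])
      mu_b <- sp_base[[sp]] + if (hab == "urban") urb_shift[[sp]] else 0
      cl <- climate[climate$site_id == site, ]
      y <- mu_b + bdev + u_site[[site]] + u_date +
        beta_tmin * cl$tmin_z + beta_precip * cl$precip_z +
        rnorm(n_days, 0, within_sd[[hab]])
      rows[[length(rows) + 1L]] <- data.frame(
        bird_id = sprintf("%s_b%03d", substr(hab, 1, 1), j),
        species = sp, habitat = hab, site_id = site,
        sex = if (sp %in% SEXABLE_SPECIES) {
          # alternate sex across successive birds of the same species
          if (((j - 1L) %/% length(cfg$species_list)) %% 2L == 0L) "M" else "F"
        } else NA_character_,
        date = dates, season = cfg$season, year = cfg$year,
        tmin_c = cl$tmin_c, precip_mm = cl$precip_mm,
        between_dev_h = bdev, y_h = y,
        stringsAsFactors = FALSE
      )
    }
  }
  setDF(rbindlist(rows))
}

#' Simulate diurnal/nocturnal activity counts from the bivariate trait model
#'
#' Draws paired binomial activity counts (active slots out of scored slots)
#' for each bird-day with bird-level and observation-level (within-bird)
#' random effects on the logit scale, optionally correlated between the two
#' windows within each habitat. Used for recovery and calibration of the
#' activity GLMMs and the bivariate diurnal-nocturnal model.
#'
#' @param n_birds_per_habitat,n_days design size.
#' @param mu_logit named list per habitat of c(diurnal, nocturnal) logit
#'   intercepts.
#' @param sigma_b,sigma_w named list per habitat of c(diurnal, nocturnal)
#'   SDs of bird effects / observation-level effects (logit scale).
#' @param rho_b,rho_w named numeric per habitat: correlation of the bird /
#'   observation-level effects across windows.
#' @param n_diurnal,n_nocturnal scored slots per window per bird-day.
#' @param seed integer seed.
#' @return data.frame with one row per bird-day and columns for both
#'   windows' counts: `n_active_diurnal`, `n_scored_diurnal`,
#'   `n_active_nocturnal`, `n_scored_nocturnal`, plus design columns.
#' @export
simulate_activity_counts <- function(n_birds_per_habitat = 30L,
                                     n_days = 12L,
                                     mu_logit = list(
                                       urban = c(qlogis(0.485), qlogis(0.041)),
                                       forest = c(qlogis(0.497), qlogis(0.016))),
                                     sigma_b = list(urban = c(0.4, 0.6),
                                                    forest = c(0.6, 0.8)),
                                     sigma_w = list(urban = c(0.5, 0.8),
                                                    forest = c(0.7, 1.0)),
                                     rho_b = c(urban = 0, forest = 0),
                                     rho_w = c(urban = 0, forest = 0),
                                     n_diurnal = 120L,
                                     n_nocturnal = 80L,
                                     seed = 1L) {
  set.seed(seed)
  cfg <- sim_config()
  sites <- default_sites(2L)
  dates <- season_start_date("pre_breeding", "2020") + seq_len(n_days) - 1L
  rmvn2 <- function(n, sd, rho) {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    cbind(sd[1] * z1, sd[2] * z2)
  }
  rows <- list()
  for (hab in c("urban", "forest")) {
    hs <- sites$site_id[sites$habitat == hab]
    b <- rmvn2(n_birds_per_habitat, sigma_b[[hab]], rho_b[[hab]])
    for (j in seq_len(n_birds_per_habitat)) {
      sp <- cfg$species_list[(j - 1L) %% 6L + 1L]
      w <- rmvn2(n_days, sigma_w[[hab]], rho_w[[hab]])
      eta_d <- mu_logit[[hab]][1] + b[j, 1] + w[, 1]
      eta_n <- mu_logit[[hab]][2] + b[j, 2] + w[, 2]
      rows[[length(rows) + 1L]] <- data.frame(
        bird_id = sprintf("%s_b%03d", substr(hab, 1, 1), j),
        species = sp, habitat = hab,
        site_id = hs[(j - 1L) %% length(hs) + 1L],
        date = dates, season = "pre_breeding", year = "2020",
        tmin_c = 0, precip_mm = 0,
        n_active_diurnal = rbinom(n_days, n_diurnal, plogis(eta_d)),
        n_scored_diurnal = n_diurnal,
        n_active_nocturnal = rbinom(n_days, n_nocturnal, plogis(eta_n)),
        n_scored_nocturnal = n_nocturnal,
        stringsAsFactors = FALSE
      )
    }
  }
  setDF(rbindlist(rows))
}
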