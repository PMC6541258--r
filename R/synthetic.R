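#' Ground-truth parameters for one simulated species
#'
#' Encodes the data-generating assumptions of the daily detection model:
#' a station is occupied with probability `psi`; on each active day of an
#' occupied station the species is detected with probability
#' `plogis(beta0 + beta_attract * attractant_age)`, where attractant age
#' is whole days since the last refresh; detected days produce
#' `1 + Poisson(extra_visits)` capture timestamps with times-of-day drawn
#' from a 1-2 component von Mises mixture.
#'
#' @param name Species label.
#' @param psi Occupancy probability in `[0, 1]`.
#' @param beta0 Baseline detection logit.
#' @param beta_attract Per-day effect of attractant age on the detection
#'   logit (negative: detection decays as the attractant ages).
#' @param diel List with numeric `mean` (hours), `kappa` (> 0) and
#'   `weight` (sums to 1) of equal length 1 or 2.
#' @param extra_visits Mean of the Poisson count of extra same-day
#'   visits. Default 0 (exactly one visit per detection day); positive
#'   values are a clustering stressor.
#' @return A list of class `species_truth`.
#' @export
species_truth <- function(name, psi, beta0, beta_attract = 0,
                          diel = list(mean = 1, kappa = 2, weight = 1),
                          extra_visits = 0) {
  stopifnot(psi >= 0, psi <= 1,
            length(diel$mean) == length(diel$kappa),
            length(diel$mean) == length(diel$weight),
            all(diel$kappa > 0),
            abs(sum(diel$weight) - 1) < 1e-8,
            extra_visits >= 0)
  structure(
    list(name = name, psi = psi, beta0 = beta0, beta_attract = beta_attract,
         diel = diel, extra_visits = extra_visits),
    class = "species_truth"
  )
}

#' A default simulated forest-carnivore community
#'
#' Four species spanning the behaviours the analysis targets: a nocturnal
#' scavenger whose detection decays as bait ages, a bimodally nocturnal
#' species with a stronger decay, a cathemeral generalist with a weak
#' decay, and a diurnal prey species that avoids fresh attractant
#' (detection increases with attractant age).
#'
#' @return List of [species_truth()] objects.
#' @export
default_community <- function() {
  list(
    species_truth("civet", psi = 0.5, beta0 = qlogis(0.10), beta_attract = -0.15,
                  diel = list(mean = 1, kappa = 2, weight = 1)),
    species_truth("genet", psi = 0.5, beta0 = qlogis(0.12), beta_attract = -0.20,
                  diel = list(mean = c(21, 3), kappa = c(3, 3), weight = c(0.5, 0.5))),
    species_truth("mongoose", psi = 0.7, beta0 = qlogis(0.15), beta_attract = -0.05,
                  diel = list(mean = 12, kappa = 0.5, weight = 1)),
    species_truth("duiker", psi = 0.6, beta0 = qlogis(0.07), beta_attract = 0.10,
                  diel = list(mean = c(7, 17), kappa = c(2.5, 2.5), weight = c(0.5, 0.5)))
  )
}

#' Configuration of a simulated camera-trap survey
#'
#' Defaults emulate the survey design the analysis assumes: 45 stations,
#' deployments of 60-90 days, attractant serviced roughly weekly with
#' refresh intervals of 3 + Gamma(2.5, scale 2) days clipped to 3-27 days
#' (mean 8 d), and a small chance a station is inactive on any given day.
#'
#' @param n_stations Number of camera stations.
#' @param deployment_days Range (min, max) of deployment lengths in days.
#' @param refresh_mean_days Mean refresh interval.
#' @param refresh_range_days Range (min, max) the intervals are clipped to.
#' @param inactive_prob Daily probability a station is non-functional.
#' @param species List of [species_truth()] objects.
#' @param start_date First possible deployment start.
#' @param start_stagger_days Deployment starts are spread uniformly over
#'   this many days.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_stations = 45,
                            deployment_days = c(60, 90),
                            refresh_mean_days = 8,
                            refresh_range_days = c(3, 27),
                            inactive_prob = 0.02,
                            species = default_community(),
                            start_date = as.Date("2013-06-01"),
                            start_stagger_days = 14) {
  stopifnot(n_stations >= 1,
            deployment_days[1] >= 1, deployment_days[1] <= deployment_days[2],
            refresh_range_days[1] > 0, refresh_range_days[1] <= refresh_range_days[2],
            refresh_mean_days > refresh_range_days[1],
            inactive_prob >= 0, inactive_prob < 1)
  if (length(species) == 0) abort("species list must not be empty")
  structure(
    list(n_stations = as.integer(n_stations),
         deployment_days = deployment_days,
         refresh_mean_days = refresh_mean_days,
         refresh_range_days = refresh_range_days,
         inactive_prob = inactive_prob,
         species = species,
         start_date = as.Date(start_date),
         start_stagger_days = start_stagger_days),
    class = "scenario_config"
  )
}

#' Null and effect scenarios
#'
#' `generate_null_scenario()` zeroes every species' attractant effect
#' (the type-I calibration input); `generate_effect_scenario()` sets it
#' to `effect_size` for every species (an effect size of 0 reduces to the
#' null scenario).
#'
#' @param config A [scenario_config()].
#' @param effect_size Per-day attractant-age effect on the detection logit.
#' @return A modified `scenario_config`.
#' @export
generate_null_scenario <- function(config = scenario_config()) {
  config$species <- lapply(config$species, function(s) { s$beta_attract <- 0; s })
  config
}

#' @rdname generate_null_scenario
#' @export
generate_effect_scenario <- function(config = scenario_config(), effect_size = -0.3) {
  config$species <- lapply(config$species, function(s) { s$beta_attract <- effect_size; s })
  config
}

#' Generate a complete synthetic camera-trap survey
#'
#' Draws deployments, refresh logs and capture records that are mutually
#' consistent (captures fall inside deployments on active days; every
#' station's refresh log starts with the installation baiting at
#' deployment start) together with the generating truth. Output is
#' byte-identical for a fixed seed.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @return An object of class `lure_survey`: list with tibbles
#'   `captures`, `deployments`, `refresh_log` and a `truth` list.
#' @export
generate_survey <- function(config, seed) {
  if (length(config$species) == 0) abort("species list must not be empty")
  withr::with_seed(seed, {
    dep <- simulate_deployments(config)
    ref <- simulate_refresh_log(config, dep)
    age <- build_covariate_matrix("attractant_age", dep, ref)
    caps <- purrr::map(config$species, simulate_species_captures,
                       deployments = dep, age = age)
    caps <- bind_rows(caps)
  })
  caps <- arrange(caps, .data$species, .data$station_id, .data$timestamp)
  truth <- list(
    species = lapply(config$species, unclass),
    n_stations = config$n_stations,
    seed = seed
  )
  structure(
    list(captures = caps, deployments = dep, refresh_log = ref, truth = truth),
    class = "lure_survey"
  )
}

#' @export
print.lure_survey <- function(x, ...) {
  cat(sprintf("<lure_survey> %d stations, %d trap-days, %d captures of %d species\n",
              nrow(x$deployments), total_trap_days(x$deployments),
              nrow(x$captures), length(unique(x$captures$species))))
  invisible(x)
}

#' Write a synthetic survey to a directory
#'
#' Emits `captures.csv`, `deployments.csv`, `refresh.csv` and
#' `truth.json` using the same schemas the readers expect.
#'
#' @param survey A [generate_survey()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_captures(survey$captures, file.path(dir, "captures.csv"))
  write_deployments(survey$deployments, file.path(dir, "deployments.csv"))
  write_refresh_log(survey$refresh_log, file.path(dir, "refresh.csv"))
  jsonlite::write_json(survey$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# ---- internals --------------------------------------------------------------

simulate_deployments <- function(config) {
  n <- config$n_stations
  len <- sample(seq(config$deployment_days[1], config$deployment_days[2]), n, replace = TRUE)
  start <- config$start_date + sample.int(config$start_stagger_days + 1, n, replace = TRUE) - 1
  end <- start + len - 1
  inactive <- vector("list", n)
  for (i in seq_len(n)) {
    days <- seq(start[i], end[i], by = "day")
    # the installation day is always active; failures strike later days
    down <- days[-1][runif(len[i] - 1) < config$inactive_prob]
    inactive[[i]] <- down
  }
  dep <- tibble(
    station_id = sprintf("ST%03d", seq_len(n)),
    survey_id = "SIM1",
    start_date = start,
    end_date = end,
    inactive_dates = inactive
  )
  dep$trap_days <- deployment_trap_days(dep)
  dep
}

simulate_refresh_log <- function(config, deployments) {
  shape <- 2.5
  scale <- (config$refresh_mean_days - config$refresh_range_days[1]) / shape
  out <- vector("list", nrow(deployments))
  for (i in seq_len(nrow(deployments))) {
    span <- as.integer(deployments$end_date[i] - deployments$start_date[i]) + 1L
    n_max <- ceiling(span / config$refresh_range_days[1]) + 1L
    gaps <- pmin(config$refresh_range_days[1] + rgamma(n_max, shape = shape, scale = scale),
                 config$refresh_range_days[2])
    offsets <- cumsum(round(gaps))
    offsets <- offsets[offsets < span]
    # installation baiting at deployment start (00:00), services at 12:00
    times <- c(as.POSIXct(deployments$start_date[i], tz = "UTC"),
               as.POSIXct(deployments$start_date[i], tz = "UTC") + offsets * 86400 + 12 * 3600)
    out[[i]] <- tibble(station_id = deployments$station_id[i], timestamp = times)
  }
  bind_rows(out)
}

# inverse-CDF draw from a von Mises mixture over time-of-day, using the
# caller's RNG stream
sample_diel <- function(diel, n) {
  if (n == 0) return(numeric(0))
  grid <- seq(0, 2 * pi, length.out = 2049)
  mu <- diel$mean * 2 * pi / 24
  dens <- rep(0, length(grid))
  for (c in seq_along(mu)) {
    dens <- dens + diel$weight[c] * vm_density(grid - mu[c], diel$kappa[c])
  }
  step <- grid[2] - grid[1]
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * step))
  cdf <- cdf / cdf[length(cdf)]
  u <- runif(n)
  (approx(cdf, grid, xout = u, rule = 2, ties = "ordered")$y * 24 / (2 * pi)) %% 24
}

simulate_species_captures <- function(truth, deployments, age) {
  active <- !is.na(age$x)
  occupied <- rbinom(nrow(deployments), 1, truth$psi) == 1
  cell_ok <- active & matrix(occupied, nrow = nrow(active), ncol = ncol(active))
  p <- plogis(truth$beta0 + truth$beta_attract * age$x)
  det <- cell_ok & matrix(rbinom(length(p), 1, ifelse(is.na(p), 0, p)) == 1,
                          nrow = nrow(p))
  idx <- which(det, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble(species = character(0), station_id = character(0),
                  timestamp = as.POSIXct(character(0), tz = "UTC"),
                  survey_id = character(0)))
  }
  n_vis <- 1L + rpois(nrow(idx), truth$extra_visits)
  row_rep <- rep(seq_len(nrow(idx)), n_vis)
  hrs <- sample_diel(truth$diel, length(row_rep))
  dates <- age$dates[idx[row_rep, 2]]
  tibble(
    species = truth$name,
    station_id = age$station_ids[idx[row_rep, 1]],
    timestamp = as.POSIXct(dates, tz = "UTC") + round(hrs * 3600),
    survey_id = "SIM1"
  )
}
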