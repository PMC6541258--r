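# Small in-code fixture builders shared across the suite.

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

make_captures <- function(species, station_id, timestamp, survey_id = "S1") {
  tibble::tibble(
    species = species,
    station_id = station_id,
    timestamp = ts_utc(timestamp),
    survey_id = survey_id
  )
}

make_deployments <- function(station_id, start_date, end_date,
                             inactive = vector("list", length(station_id)),
                             survey_id = "S1") {
  inactive <- lapply(inactive, function(d) if (is.null(d)) as.Date(character(0)) else as.Date(d))
  dep <- tibble::tibble(
    station_id = station_id,
    survey_id = survey_id,
    start_date = as.Date(start_date),
    end_date = as.Date(end_date),
    inactive_dates = inactive
  )
  dep$trap_days <- deployment_trap_days(dep)
  dep
}

make_refresh <- function(station_id, timestamp) {
  tibble::tibble(station_id = station_id, timestamp = ts_utc(timestamp))
}

# Independent likelihood oracle: explicit sum over the latent occupancy
# state of each site, plain products, no logs, no shared code with the
# package implementation.
oracle_negloglik <- function(beta_psi, beta_p, y, X = list()) {
  psi <- 1 / (1 + exp(-beta_psi))
  lik <- 1
  for (i in seq_len(nrow(y))) {
    site_lik <- 0
    for (z in c(0, 1)) {
      pr_z <- if (z == 1) psi else 1 - psi
      pr_hist <- 1
      for (j in seq_len(ncol(y))) {
        if (is.na(y[i, j])) next
        eta <- beta_p[1]
        if (length(X) > 0) {
          for (t in seq_along(X)) eta <- eta + beta_p[1 + t] * X[[t]][i, j]
        }
        p <- if (z == 1) 1 / (1 + exp(-eta)) else 0
        pr_hist <- pr_hist * (if (y[i, j] == 1) p else 1 - p)
      }
      site_lik <- site_lik + pr_z * pr_hist
    }
    lik <- lik * site_lik
  }
  -log(lik)
}

# Trapezoid integral of a fitted activity density over the full cycle.
trapz_circle <- function(act) {
  f <- c(act$density, act$density[1])
  sum((f[-1] + f[-length(f)]) / 2) * 2 * pi / length(act$density)
}

circ_diff_hours <- function(a, b) {
  d <- abs(a - b) %% 24
  min(d, 24 - d)
}

# A single-species survey configuration used by the recovery experiments.
recovery_config <- function(n_stations, days, psi, p0, beta_attract,
                            inactive_prob = 0) {
  scenario_config(
    n_stations = n_stations,
    deployment_days = c(days, days),
    inactive_prob = inactive_prob,
    start_stagger_days = 0,
    species = list(species_truth(
      "focal", psi = psi, beta0 = qlogis(p0), beta_attract = beta_attract,
      diel = list(mean = 1, kappa = 1.5, weight = 1)
    ))
  )
}

# One replicate of generate -> process -> fit for the focal species.
fit_focal_replicate <- function(config, seed, terms = "attractant_age",
                                control = occu_control(n_starts = 2)) {
  sv <- generate_survey(config, seed)
  ind <- filter_independent(sv$captures)
  dm <- build_detection_matrix(ind, sv$deployments, "focal")
  covs <- list(attractant_age = build_covariate_matrix("attractant_age",
                                                       sv$deployments, sv$refresh_log))
  fit_occupancy(dm, covs, terms, control)
}
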