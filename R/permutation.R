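#' Observed proportion of visits in each day bin since refresh
#'
#' Divides the number of independent site visits in each 24-h bin (days
#' 1..`max_bin_days` since attractant refresh) by the total independent
#' captures of the species — including captures beyond the bin horizon,
#' so the proportions need not sum to 1.
#'
#' @param captures Independent captures of one species carrying a
#'   `day_bin` column (see [add_refresh_age()]).
#' @param max_bin_days Number of bins.
#' @return Numeric vector of length `max_bin_days`.
#' @export
observed_proportions <- function(captures, max_bin_days = 7) {
  if (!"day_bin" %in% names(captures)) abort("captures must carry a day_bin column")
  total <- nrow(captures)
  if (total == 0) return(rep(0, max_bin_days))
  counts <- tabulate(captures$day_bin[!is.na(captures$day_bin)], nbins = max_bin_days)
  counts / total
}

#' Generate random capture histories under the no-response null
#'
#' Each random capture is built by drawing, independently: a station
#' uniformly from the stations at which the species was captured, a date
#' uniformly from that station's active dates, and a time-of-day from the
#' species' fitted diel activity density. Elapsed time since refresh is
#' then computed exactly as for observed captures. This breaks any link
#' between visitation and attractant age while preserving the species'
#' diel rhythm, the spatial footprint of its captures, and the stations'
#' refresh schedules.
#'
#' @param n_caps Captures per history (the observed sample size).
#' @param n_histories Number of histories N.
#' @param stations Stations at which the species was captured.
#' @param deployments Deployment table (must cover `stations`).
#' @param refresh_log Refresh table.
#' @param density Fitted [fit_activity()] density.
#' @param seed Integer seed.
#' @param max_bin_days Bin horizon.
#' @return List with `props` (`n_histories` by `max_bin_days` matrix of
#'   bin proportions, denominator `n_caps`), `hours` (elapsed time of
#'   every draw) and `station` (station of every draw).
#' @export
generate_random_histories <- function(n_caps, n_histories, stations, deployments,
                                      refresh_log, density, seed,
                                      max_bin_days = 7) {
  stopifnot(n_caps >= 1, n_histories >= 1)
  dep <- deployments[match(stations, deployments$station_id), , drop = FALSE]
  if (anyNA(dep$station_id)) abort("every capture station must appear in the deployments")
  grid <- occasion_grid(dep)
  date_pool <- list()
  for (i in seq_along(stations)) {
    date_pool[[i]] <- grid$dates[grid$active[i, ]]
  }
  n_dates <- lengths(date_pool)
  pool <- do.call(c, date_pool)
  offset <- cumsum(c(0, n_dates[-length(n_dates)]))

  total <- n_caps * n_histories
  draws <- withr::with_seed(seed, {
    draw_one <- function(n) {
      s <- sample.int(length(stations), n, replace = TRUE)
      didx <- floor(runif(n) * n_dates[s]) + 1
      u <- runif(n)
      hrs <- (approx(density$cdf, density$cdf_x, xout = u, rule = 2, ties = "ordered")$y * 24 / (2 * pi)) %% 24
      times <- as.POSIXct(pool[offset[s] + didx], tz = "UTC") + hrs * 3600
      list(sid = s, elapsed = elapsed_since_refresh(times, stations[s], refresh_log,
                                                    strict = FALSE))
    }
    d <- draw_one(total)
    # a draw before the station's first logged refresh is invalid: resample it
    for (tries in 1:100) {
      bad <- which(is.na(d$elapsed))
      if (length(bad) == 0) break
      redo <- draw_one(length(bad))
      d$sid[bad] <- redo$sid
      d$elapsed[bad] <- redo$elapsed
    }
    if (anyNA(d$elapsed)) {
      abort("could not draw random captures after a station's first refresh; check the refresh log covers deployments")
    }
    d
  })
  sid <- draws$sid
  elapsed <- draws$elapsed
  bins <- assign_day_bin(elapsed, max_bin_days)
  hist_id <- rep(seq_len(n_histories), each = n_caps)
  ok <- !is.na(bins)
  counts <- tabulate((hist_id[ok] - 1L) * max_bin_days + bins[ok],
                     nbins = n_histories * max_bin_days)
  props <- matrix(counts, nrow = n_histories, ncol = max_bin_days, byrow = TRUE) / n_caps
  list(props = props, hours = elapsed, station = stations[sid])
}

#' Permutation p-value of an observed bin proportion
#'
#' Rank-style probability `p = (#{random < observed} + 0.5 #ties + 1) /
#' (N + 1)`, in (0, 1]. Low p means the observed proportion sits below the
#' null (sites visited less often than expected); high p means above it.
#' Ties count half to avoid discreteness bias.
#'
#' @param observed Observed proportion (scalar).
#' @param random Numeric vector of null proportions.
#' @return The p-value.
#' @export
permutation_pvalue <- function(observed, random) {
  N <- length(random)
  stopifnot(N >= 1)
  (sum(random < observed) + 0.5 * sum(random == observed) + 1) / (N + 1)
}

#' Classify a short-term visitation response
#'
#' Two-tailed at level `alpha`: `p < alpha/2` means sites were visited
#' less often than the null predicts (`"decreased"`), `p > 1 - alpha/2`
#' more often (`"increased"`), otherwise `"none"`.
#'
#' @param p Permutation p-value(s).
#' @param alpha Two-tailed significance level (default 0.05, i.e.
#'   thresholds 0.025 and 0.975).
#' @return Character vector in `{"decreased", "none", "increased"}`.
#' @export
classify_response <- function(p, alpha = 0.05) {
  dplyr::case_when(
    p < alpha / 2 ~ "decreased",
    p > 1 - alpha / 2 ~ "increased",
    .default = "none"
  )
}

#' Permutation test of short-term visitation response to refresh
#'
#' Compares the observed proportion of a species' independent site visits
#' in each of the 7 days after attractant refresh against `N` random
#' capture histories of the same sample size (see
#' [generate_random_histories()]).
#'
#' @param captures Independent captures of one species with `day_bin` and
#'   `hours_since_refresh` columns.
#' @param deployments Deployment table.
#' @param refresh_log Refresh table.
#' @param density Optional [fit_activity()] density; fitted from the
#'   captures' times-of-day when omitted (requires >= 10 captures).
#' @param n_randomizations Number of random histories N.
#' @param alpha Two-tailed significance level.
#' @param seed Integer seed.
#' @param max_bin_days Bin horizon.
#' @return An object of class `perm_test`.
#' @export
permutation_test <- function(captures, deployments, refresh_log, density = NULL,
                             n_randomizations = 1000, alpha = 0.05, seed = 1L,
                             max_bin_days = 7) {
  species <- unique(captures$species)
  if (length(species) != 1) abort("captures must contain exactly one species")
  if (is.null(density)) density <- fit_activity(captures$timestamp)
  stations <- sort(unique(captures$station_id))
  obs <- observed_proportions(captures, max_bin_days)
  rnd <- generate_random_histories(nrow(captures), n_randomizations, stations,
                                   deployments, refresh_log, density, seed,
                                   max_bin_days)
  p <- vapply(seq_len(max_bin_days),
              function(d) permutation_pvalue(obs[d], rnd$props[, d]), numeric(1))
  structure(
    list(species = species, observed = obs, random = rnd$props,
         p_values = p, classification = classify_response(p, alpha),
         n_captures = nrow(captures), N = n_randomizations,
         alpha = alpha, seed = seed),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> %s: %d captures, N = %d randomizations\n",
              x$species, x$n_captures, x$N))
  print(tidy(x), n = length(x$observed))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.perm_test <- function(x, ...) {
  tibble(
    day = seq_along(x$observed),
    observed = x$observed,
    null_mean = colMeans(x$random),
    null_lo = apply(x$random, 2, stats::quantile, 0.025),
    null_hi = apply(x$random, 2, stats::quantile, 0.975),
    p.value = x$p_values,
    classification = x$classification
  )
}

#' @exportS3Method generics::glance
glance.perm_test <- function(x, ...) {
  tibble(
    species = x$species,
    n_captures = x$n_captures,
    N = x$N,
    alpha = x$alpha,
    n_increased = sum(x$classification == "increased"),
    n_decreased = sum(x$classification == "decreased")
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.perm_test <- function(object, ...) {
  null_long <- tibble(
    day = rep(seq_len(ncol(object$random)), each = nrow(object$random)),
    proportion = as.vector(object$random)
  )
  obs <- tibble(day = seq_along(object$observed), proportion = object$observed,
                classification = object$classification)
  ggplot2::ggplot(null_long, ggplot2::aes(x = factor(.data$day), y = .data$proportion)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey60") +
    ggplot2::geom_point(data = obs, ggplot2::aes(colour = .data$classification), size = 2) +
    ggplot2::scale_colour_manual(values = c(decreased = "#d7301f", none = "grey30",
                                            increased = "#0570b0")) +
    ggplot2::labs(x = "Days since attractant refresh", y = "Proportion of site visits",
                  title = object$species)
}
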