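#' Reduce a capture log to independent captures
#'
#' A capture is independent if at least `window_hours` have elapsed since
#' the previously *retained* capture of the same species at the same
#' station (sliding-anchor convention). The first capture of each
#' species-station series is always retained, and retained captures are
#' therefore pairwise at least `window_hours` apart, which makes the
#' filter idempotent.
#'
#' @param captures Capture tibble (see [read_captures()]).
#' @param window_hours Independence window in hours (default 1).
#' @return The retained rows, in (species, station_id, timestamp) order.
#' @export
filter_independent <- function(captures, window_hours = 1) {
  stopifnot(window_hours > 0)
  if (nrow(captures) == 0) return(captures)
  caps <- arrange(captures, .data$species, .data$station_id, .data$timestamp)
  key <- paste(caps$species, caps$station_id, sep = "\r")
  secs <- as.numeric(caps$timestamp)
  keep <- logical(nrow(caps))
  win <- window_hours * 3600
  for (idx in split(seq_len(nrow(caps)), key)) {
    anchor <- -Inf
    for (i in idx) {
      if (secs[i] - anchor >= win) {
        keep[i] <- TRUE
        anchor <- secs[i]
      }
    }
  }
  caps[keep, , drop = FALSE]
}

#' Time elapsed since the most recent attractant refresh
#'
#' For each capture, the elapsed time (hours) since the most recent
#' refresh event at that station at or before the capture, and the 24-h
#' day bin it falls in. Bin d covers hours `[24(d-1), 24d)`; captures at
#' or beyond `24 * max_bin_days` hours get bin `NA` (excluded from the
#' short-term analysis, which is restricted to one week).
#'
#' @param captures Capture tibble.
#' @param refresh_log Refresh tibble (see [read_refresh_log()]).
#' @param max_bin_days Bin horizon in days (default 7).
#' @return `captures` with `hours_since_refresh` and `day_bin` columns.
#' @export
add_refresh_age <- function(captures, refresh_log, max_bin_days = 7) {
  h <- elapsed_since_refresh(captures$timestamp, captures$station_id, refresh_log)
  captures$hours_since_refresh <- h
  captures$day_bin <- assign_day_bin(h, max_bin_days)
  captures
}

#' @rdname add_refresh_age
#' @param times POSIXct vector of event times.
#' @param station_ids Station of each event.
#' @param strict Error on an event with no prior refresh (`TRUE`, the
#'   default) or return `NA` for it.
#' @export
elapsed_since_refresh <- function(times, station_ids, refresh_log, strict = TRUE) {
  out <- rep(NA_real_, length(times))
  secs <- as.numeric(times)
  ref_secs <- split(as.numeric(refresh_log$timestamp), refresh_log$station_id)
  ref_secs <- lapply(ref_secs, sort)
  for (sid in unique(station_ids)) {
    i <- which(station_ids == sid)
    rs <- ref_secs[[sid]]
    if (is.null(rs)) {
      abort(sprintf("no refresh events logged for station '%s'", sid))
    }
    pos <- findInterval(secs[i], rs)
    if (any(pos == 0) && strict) {
      j <- i[which(pos == 0)[1]]
      abort(sprintf("capture at station '%s' (%s) precedes the first logged refresh",
                    sid, format(times[j])))
    }
    hit <- pos > 0
    out[i[hit]] <- (secs[i][hit] - rs[pos[hit]]) / 3600
  }
  out
}

#' Map hours-since-refresh to a 24-h day bin
#'
#' @param hours Non-negative numeric vector.
#' @param max_bin_days Bins beyond this horizon are `NA`.
#' @return Integer bins 1..`max_bin_days`, `NA` at or past the horizon.
#' @export
assign_day_bin <- function(hours, max_bin_days = 7) {
  stopifnot(all(hours >= 0, na.rm = TRUE))
  bin <- floor(hours / 24) + 1L
  bin[bin > max_bin_days] <- NA_integer_
  as.integer(bin)
}

#' Occasion grid shared by detection and covariate matrices
#'
#' Stations by calendar dates spanning all deployments, with an activity
#' mask: a cell is active when the date lies in the station's deployment
#' window and is not an inactive date.
#'
#' @param deployments Deployment table.
#' @return List with `station_ids`, `dates`, and logical matrix `active`.
#' @export
occasion_grid <- function(deployments) {
  dates <- seq(min(deployments$start_date), max(deployments$end_date), by = "day")
  sids <- deployments$station_id
  active <- matrix(FALSE, nrow = length(sids), ncol = length(dates),
                   dimnames = list(sids, format(dates)))
  for (i in seq_along(sids)) {
    in_window <- dates >= deployments$start_date[i] & dates <= deployments$end_date[i]
    active[i, ] <- in_window & !(dates %in% deployments$inactive_dates[[i]])
  }
  list(station_ids = sids, dates = dates, active = active)
}

#' Build a daily detection history for one species
#'
#' Cells are 1 if the station recorded at least one independent capture of
#' the species on that date, 0 if it was active but recorded none, and
#' `NA` (missing occasion) if the station was not active that date.
#'
#' @param captures Independent captures (all species; filtered internally
#'   by `species`).
#' @param deployments Deployment table.
#' @param species Species name.
#' @return An object of class `detection_matrix`.
#' @export
build_detection_matrix <- function(captures, deployments, species) {
  grid <- occasion_grid(deployments)
  y <- matrix(NA_integer_, nrow = length(grid$station_ids), ncol = length(grid$dates),
              dimnames = dimnames(grid$active))
  y[grid$active] <- 0L
  caps <- captures[captures$species == species, , drop = FALSE]
  if (nrow(caps) > 0) {
    ri <- match(caps$station_id, grid$station_ids)
    if (anyNA(ri)) {
      abort(sprintf("capture of '%s' at station '%s' absent from deployments",
                    species, caps$station_id[which(is.na(ri))[1]]))
    }
    ci <- match(as.Date(caps$timestamp), grid$dates)
    ok <- !is.na(ci)
    hit <- cbind(ri[ok], ci[ok])
    hit <- hit[!is.na(y[hit]), , drop = FALSE]  # captures on inactive dates stay missing
    y[hit] <- 1L
  }
  structure(
    list(species = species, y = y, station_ids = grid$station_ids, dates = grid$dates),
    class = "detection_matrix"
  )
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat(sprintf("<detection_matrix> %s: %d stations x %d occasions, %d detections, %d missing cells\n",
              x$species, nrow(x$y), ncol(x$y), sum(x$y == 1L, na.rm = TRUE), sum(is.na(x$y))))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.detection_matrix <- function(x, ...) {
  tibble(
    station_id = rep(x$station_ids, times = length(x$dates)),
    date = rep(x$dates, each = length(x$station_ids)),
    y = as.integer(x$y)
  )
}

#' Build a detection covariate matrix aligned with the occasion grid
#'
#' Three observation-level covariates of the daily detection model:
#' \describe{
#'   \item{attractant_age}{Whole days since the most recent refresh date at
#'     or before each occasion (0 on refresh dates).}
#'   \item{incremental_effort}{Number of days the station had been
#'     effectively active from installation up to and including the
#'     occasion; runs from 1 to the station's total trap-days, skipping
#'     inactive days.}
#'   \item{total_effort}{The station's total active trap-days, constant
#'     across its row.}
#' }
#' Cells on missing occasions are `NA`.
#'
#' @param kind One of `"attractant_age"`, `"incremental_effort"`,
#'   `"total_effort"`.
#' @param deployments Deployment table.
#' @param refresh_log Refresh table; required for `attractant_age`.
#' @return An object of class `covariate_matrix`.
#' @export
build_covariate_matrix <- function(kind = c("attractant_age", "incremental_effort", "total_effort"),
                                   deployments, refresh_log = NULL) {
  kind <- match.arg(kind)
  grid <- occasion_grid(deployments)
  x <- matrix(NA_real_, nrow = length(grid$station_ids), ncol = length(grid$dates),
              dimnames = dimnames(grid$active))
  if (kind == "attractant_age") {
    if (is.null(refresh_log)) abort("attractant_age requires a refresh log")
    ref_dates <- split(as.Date(refresh_log$timestamp), refresh_log$station_id)
    for (i in seq_along(grid$station_ids)) {
      sid <- grid$station_ids[i]
      rd <- sort(unique(ref_dates[[sid]]))
      act <- which(grid$active[i, ])
      if (length(act) == 0) next
      if (is.null(rd) || min(grid$dates[act]) < min(rd)) {
        abort(sprintf("station '%s' has active occasions before its first refresh", sid))
      }
      pos <- findInterval(as.numeric(grid$dates[act]), as.numeric(rd))
      x[i, act] <- as.numeric(grid$dates[act] - rd[pos])
    }
  } else if (kind == "incremental_effort") {
    for (i in seq_along(grid$station_ids)) {
      act <- which(grid$active[i, ])
      x[i, act] <- seq_along(act)
    }
  } else {
    days <- deployment_trap_days(deployments)
    for (i in seq_along(grid$station_ids)) {
      x[i, grid$active[i, ]] <- days[i]
    }
  }
  structure(
    list(kind = kind, x = x, station_ids = grid$station_ids, dates = grid$dates),
    class = "covariate_matrix"
  )
}

#' @export
print.covariate_matrix <- function(x, ...) {
  rng <- range(x$x, na.rm = TRUE)
  cat(sprintf("<covariate_matrix> %s: %d stations x %d occasions, range [%g, %g]\n",
              x$kind, nrow(x$x), ncol(x$x), rng[1], rng[2]))
  invisible(x)
}

#' Capture rate per 100 trap-days
#'
#' @param n_independent Number of independent captures.
#' @param trap_days Survey effort in active trap-days (> 0).
#' @return `100 * n_independent / trap_days`.
#' @export
capture_rate <- function(n_independent, trap_days) {
  stopifnot(all(trap_days > 0))
  100 * n_independent / trap_days
}

#' Naive occupancy and detection, uncorrected for imperfect detection
#'
#' Naive occupancy is the fraction of stations with at least one
#' detection; naive detection is the fraction of non-missing occasions
#' with a detection.
#'
#' @param detection_matrix A [build_detection_matrix()] result.
#' @return A one-row tibble with `naive_occupancy` and `naive_detection`.
#' @export
naive_summaries <- function(detection_matrix) {
  y <- detection_matrix$y
  tibble(
    naive_occupancy = mean(apply(y, 1, function(r) any(r == 1L, na.rm = TRUE))),
    naive_detection = mean(y, na.rm = TRUE)
  )
}
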