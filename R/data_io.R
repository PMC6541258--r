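#' Read a camera-trap capture log
#'
#' Reads a CSV of photo events with columns `species`, `station_id`,
#' `timestamp` (ISO-8601, minute resolution or finer) and `survey_id`.
#' Timestamps are naive local clock time (the diel analysis assumes a
#' single local clock); they are stored as UTC-tagged POSIXct so no
#' daylight-saving arithmetic is ever applied.
#'
#' @param path Path to a CSV file with a header row.
#' @param deployments Optional deployment table (see [read_deployments()]).
#'   When supplied, captures falling outside their station's deployment
#'   window are flagged in an `in_deployment` column and a warning is
#'   raised; the records are retained.
#' @return A tibble with one row per capture, sorted by
#'   (species, station_id, timestamp).
#' @export
read_captures <- function(path, deployments = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  require_columns(raw, c("species", "station_id", "timestamp", "survey_id"), "capture log")
  ts <- parse_timestamp(raw$timestamp, path)
  caps <- tibble(
    species = raw$species,
    station_id = raw$station_id,
    timestamp = ts,
    survey_id = raw$survey_id
  )
  bad <- which(is.na(caps$species) | caps$species == "" |
                 is.na(caps$station_id) | caps$station_id == "")
  if (length(bad) > 0) {
    abort(sprintf("capture log '%s': empty species or station_id at row %d", path, bad[1]))
  }
  caps <- arrange(caps, .data$species, .data$station_id, .data$timestamp)
  if (!is.null(deployments)) {
    caps <- flag_deployment_window(caps, deployments)
  }
  caps
}

#' Read a station deployment log
#'
#' Columns: `station_id`, `survey_id`, `start_date`, `end_date` (ISO dates)
#' and `inactive_dates`, a `;`-separated list of dates on which the station
#' was not functional (may be empty). A trap-day is a calendar date on
#' which the station was active; active trap-days are the deployment span
#' minus inactive dates.
#'
#' @param path Path to a CSV file.
#' @return A tibble with `inactive_dates` as a list-column of Date vectors
#'   and a computed `trap_days` column (active days).
#' @export
read_deployments <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  require_columns(raw, c("station_id", "survey_id", "start_date", "end_date"), "deployment log")
  if (!"inactive_dates" %in% names(raw)) raw$inactive_dates <- ""
  dep <- tibble(
    station_id = raw$station_id,
    survey_id = raw$survey_id,
    start_date = parse_date_col(raw$start_date, path, "start_date"),
    end_date = parse_date_col(raw$end_date, path, "end_date"),
    inactive_dates = parse_inactive(raw$inactive_dates)
  )
  validate_deployments(dep, path)
  dep$trap_days <- deployment_trap_days(dep)
  arrange(dep, .data$station_id)
}

#' Read an attractant refresh log
#'
#' Columns: `station_id`, `timestamp`. Each row records one servicing event
#' at which bait and lure were replaced. Timestamps must be strictly
#' increasing within a station, and every station used in an analysis must
#' have a refresh at or before its first analysed occasion (the
#' installation baiting).
#'
#' @param path Path to a CSV file.
#' @return A tibble sorted by (station_id, timestamp).
#' @export
read_refresh_log <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  require_columns(raw, c("station_id", "timestamp"), "refresh log")
  ref <- tibble(
    station_id = raw$station_id,
    timestamp = parse_timestamp(raw$timestamp, path)
  )
  split_times <- split(as.numeric(ref$timestamp), ref$station_id)
  for (sid in names(split_times)) {
    if (is.unsorted(split_times[[sid]], strictly = TRUE)) {
      abort(sprintf("refresh log '%s': timestamps not strictly increasing at station '%s'", path, sid))
    }
  }
  arrange(ref, .data$station_id, .data$timestamp)
}

#' Write capture, deployment and refresh tables
#'
#' Inverse of the readers: `read_*` of a written file reproduces the input
#' table exactly (round-trip identity).
#'
#' @param captures,deployments,refresh_log Tables as returned by the readers.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_captures <- function(captures, path) {
  out <- tibble(
    species = captures$species,
    station_id = captures$station_id,
    timestamp = format(captures$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    survey_id = captures$survey_id
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_captures
#' @export
write_deployments <- function(deployments, path) {
  out <- tibble(
    station_id = deployments$station_id,
    survey_id = deployments$survey_id,
    start_date = format(deployments$start_date),
    end_date = format(deployments$end_date),
    inactive_dates = vapply(deployments$inactive_dates,
                            function(d) paste(format(d), collapse = ";"), character(1))
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_captures
#' @export
write_refresh_log <- function(refresh_log, path) {
  out <- tibble(
    station_id = refresh_log$station_id,
    timestamp = format(refresh_log$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Analysis run configuration
#'
#' Bundles the tunable constants of the pipeline: the independence window
#' (default 1 h), the occasion length (1 day), the randomization count
#' (default 1000), the day-bin horizon (7 days since refresh) and the
#' significance level (0.05, split two-tailed into 0.025/0.975).
#'
#' @param independence_window_hours Minimum spacing between independent
#'   captures of the same species at the same station, in hours.
#' @param occasion_length_days Occasion length; the daily detection model
#'   requires 1.
#' @param n_randomizations Number of random capture histories per species.
#' @param max_bin_days Number of 24-h bins since refresh analysed.
#' @param alpha Two-tailed significance level.
#' @param seed Integer seed for all randomized stages.
#' @return A list of class `lure_config`.
#' @export
run_config <- function(independence_window_hours = 1,
                       occasion_length_days = 1,
                       n_randomizations = 1000,
                       max_bin_days = 7,
                       alpha = 0.05,
                       seed = 1L) {
  stopifnot(independence_window_hours > 0,
            occasion_length_days == 1,
            n_randomizations >= 1,
            max_bin_days >= 1,
            alpha > 0, alpha < 1)
  structure(
    list(independence_window_hours = independence_window_hours,
         occasion_length_days = occasion_length_days,
         n_randomizations = as.integer(n_randomizations),
         max_bin_days = as.integer(max_bin_days),
         alpha = alpha,
         seed = as.integer(seed)),
    class = "lure_config"
  )
}

#' Active trap-days per station and in total
#'
#' @param deployments Deployment table.
#' @return `deployment_trap_days()`: integer vector of active days per row;
#'   `total_trap_days()`: their sum.
#' @export
deployment_trap_days <- function(deployments) {
  span <- as.integer(deployments$end_date - deployments$start_date) + 1L
  span - vapply(deployments$inactive_dates, length, integer(1))
}

#' @rdname deployment_trap_days
#' @export
total_trap_days <- function(deployments) {
  sum(deployment_trap_days(deployments))
}

# ---- internal helpers -------------------------------------------------------

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing required column(s): %s", what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

parse_timestamp <- function(x, path) {
  ts <- lubridate::ymd_hms(x, tz = "UTC", truncated = 1, quiet = TRUE)
  bad <- which(is.na(ts) & !is.na(x))
  if (length(bad) > 0) {
    abort(sprintf("'%s': unparseable timestamp '%s' at data row %d", path, x[bad[1]], bad[1]))
  }
  ts
}

parse_date_col <- function(x, path, col) {
  d <- lubridate::ymd(x, quiet = TRUE)
  bad <- which(is.na(d) & !is.na(x))
  if (length(bad) > 0) {
    abort(sprintf("'%s': unparseable %s '%s' at data row %d", path, col, x[bad[1]], bad[1]))
  }
  d
}

parse_inactive <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || s == "") return(as.Date(character(0)))
    sort(lubridate::ymd(strsplit(s, ";", fixed = TRUE)[[1]]))
  })
}

validate_deployments <- function(dep, path = "<deployments>") {
  bad <- which(dep$end_date < dep$start_date)
  if (length(bad) > 0) {
    abort(sprintf("'%s': end_date before start_date at station '%s'", path, dep$station_id[bad[1]]))
  }
  for (i in seq_len(nrow(dep))) {
    ia <- dep$inactive_dates[[i]]
    if (length(ia) > 0 && (min(ia) < dep$start_date[i] || max(ia) > dep$end_date[i])) {
      abort(sprintf("'%s': inactive date outside deployment window at station '%s'",
                    path, dep$station_id[i]))
    }
  }
  if (any(deployment_trap_days(dep) <= 0)) {
    abort(sprintf("'%s': a deployment has no active trap-days", path))
  }
  invisible(dep)
}

flag_deployment_window <- function(caps, deployments) {
  dep_idx <- match(caps$station_id, deployments$station_id)
  if (anyNA(dep_idx)) {
    abort(sprintf("capture at unknown station '%s'", caps$station_id[which(is.na(dep_idx))[1]]))
  }
  date <- as.Date(caps$timestamp)
  inside <- date >= deployments$start_date[dep_idx] & date <= deployments$end_date[dep_idx]
  caps$in_deployment <- inside
  if (any(!inside)) {
    warn(sprintf("%d capture(s) fall outside their station's deployment window; retained and flagged",
                 sum(!inside)))
  }
  caps
}
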