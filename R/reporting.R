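#' Per-species survey summary (independent captures, rates, naive metrics)
#'
#' One row per species: number of independent captures, capture rate per
#' 100 trap-days, naive detection (fraction of non-missing occasions with
#' a detection) and naive occupancy (fraction of stations with at least
#' one detection).
#'
#' @param captures Raw capture tibble (the independence filter is applied
#'   internally).
#' @param deployments Deployment table.
#' @param species Species to summarise; defaults to all present.
#' @param window_hours Independence window.
#' @return A tibble with columns `species`, `n_independent`,
#'   `capture_rate`, `naive_detection`, `naive_occupancy`, `trap_days`.
#' @export
table1_summary <- function(captures, deployments, species = NULL, window_hours = 1) {
  if (is.null(species)) species <- sort(unique(captures$species))
  ind <- filter_independent(captures, window_hours)
  effort <- total_trap_days(deployments)
  rows <- purrr::map(species, function(sp) {
    caps_sp <- ind[ind$species == sp, , drop = FALSE]
    dm <- build_detection_matrix(caps_sp, deployments, sp)
    nv <- naive_summaries(dm)
    tibble(
      species = sp,
      n_independent = nrow(caps_sp),
      capture_rate = capture_rate(nrow(caps_sp), effort),
      naive_detection = nv$naive_detection,
      naive_occupancy = nv$naive_occupancy,
      trap_days = effort
    )
  })
  bind_rows(rows)
}

#' Run the full attractant-effect analysis for every species
#'
#' For each species with enough independent captures: builds the daily
#' detection history and covariate matrices, fits and ranks the
#' occupancy-detection model set by AICc, fits the diel activity density,
#' and runs the refresh-response permutation test. Species with fewer
#' than `min_captures` independent captures are summarised but not
#' modelled.
#'
#' @param captures Raw capture tibble.
#' @param deployments Deployment table.
#' @param refresh_log Refresh table.
#' @param config A [run_config()].
#' @param min_captures Minimum independent captures for model fitting.
#' @return An object of class `lure_run`: list with `table1`,
#'   `model_sets`, `permutation`, `activity` (named by species),
#'   `detection_curves` (tibble) and the `config`.
#' @export
run_attractant_analysis <- function(captures, deployments, refresh_log,
                                    config = run_config(), min_captures = 10) {
  ind <- filter_independent(captures, config$independence_window_hours)
  ind <- add_refresh_age(ind, refresh_log, config$max_bin_days)
  covs <- list(
    attractant_age = build_covariate_matrix("attractant_age", deployments, refresh_log),
    total_effort = build_covariate_matrix("total_effort", deployments),
    incremental_effort = build_covariate_matrix("incremental_effort", deployments)
  )
  species <- sort(unique(ind$species))
  tab1 <- table1_summary(captures, deployments, species,
                         config$independence_window_hours)
  model_sets <- list()
  permutation <- list()
  activity <- list()
  curves <- list()
  for (k in seq_along(species)) {
    sp <- species[k]
    caps_sp <- ind[ind$species == sp, , drop = FALSE]
    if (nrow(caps_sp) < min_captures) next
    dm <- build_detection_matrix(caps_sp, deployments, sp)
    model_sets[[sp]] <- run_model_set(dm, covs)
    activity[[sp]] <- fit_activity(caps_sp$timestamp)
    permutation[[sp]] <- permutation_test(
      caps_sp, deployments, refresh_log, density = activity[[sp]],
      n_randomizations = config$n_randomizations, alpha = config$alpha,
      seed = config$seed + k, max_bin_days = config$max_bin_days)
    attr_fit <- model_sets[[sp]]$fit[[which(vapply(model_sets[[sp]]$terms, function(t)
      identical(t, "attractant_age"), logical(1)))]]
    curves[[sp]] <- predict_detection(
      attr_fit, tibble(attractant_age = seq(0, config$max_bin_days, by = 0.25))) %>%
      mutate(species = sp, .before = 1)
  }
  structure(
    list(table1 = tab1, model_sets = model_sets, permutation = permutation,
         activity = activity, detection_curves = bind_rows(curves),
         config = config),
    class = "lure_run"
  )
}

#' @export
print.lure_run <- function(x, ...) {
  cat(sprintf("<lure_run> %d species summarised, %d modelled (seed %d)\n",
              nrow(x$table1), length(x$model_sets), x$config$seed))
  invisible(x)
}

#' Write every analysis surface of a run to a directory, with a manifest
#'
#' Emits `table1.csv`, one `model_selection_<species>.csv` and
#' `permutation_<species>.csv` per modelled species,
#' `detection_curves.csv`, `activity_<species>.csv` (hour, density),
#' `run.log` and a `manifest.json` listing every file with its SHA-256
#' digest, the configuration and per-species record counts. Reruns from
#' the same inputs and seed are bit-identical.
#'
#' @param run A [run_attractant_analysis()] result.
#' @param dir Output directory.
#' @return Path of the manifest, invisibly.
#' @export
assemble_run <- function(run, dir) {
  required <- c("table1", "model_sets", "permutation", "activity",
                "detection_curves", "config")
  missing <- required[!required %in% names(run) | vapply(run[required], is.null, logical(1))]
  if (length(missing) > 0) {
    abort(sprintf("run is missing stage output(s): %s", paste(missing, collapse = ", ")))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  w <- function(df, name) {
    readr::write_csv(df, file.path(dir, name))
    files <<- c(files, name)
  }
  w(run$table1, "table1.csv")
  for (sp in names(run$model_sets)) {
    w(select(run$model_sets[[sp]], -"terms", -"fit"),
      sprintf("model_selection_%s.csv", sp))
  }
  for (sp in names(run$permutation)) {
    w(tidy(run$permutation[[sp]]), sprintf("permutation_%s.csv", sp))
    null_long <- tibble(
      day = rep(seq_len(ncol(run$permutation[[sp]]$random)),
                each = nrow(run$permutation[[sp]]$random)),
      proportion = as.vector(run$permutation[[sp]]$random)
    )
    w(null_long, sprintf("permutation_null_%s.csv", sp))
  }
  for (sp in names(run$activity)) {
    w(tidy(run$activity[[sp]]), sprintf("activity_%s.csv", sp))
  }
  w(run$detection_curves, "detection_curves.csv")
  log_lines <- c(
    sprintf("lurefx run, seed %d", run$config$seed),
    sprintf("species summarised: %d; species modelled: %d",
            nrow(run$table1), length(run$model_sets)),
    sprintf("randomizations per species: %d", run$config$n_randomizations)
  )
  writeLines(log_lines, file.path(dir, "run.log"))
  files <- c(files, "run.log")
  digests <- vapply(files, function(f)
    digest::digest(file.path(dir, f), algo = "sha256", file = TRUE), character(1))
  manifest <- list(
    config = unclass(run$config),
    counts = stats::setNames(as.list(run$table1$n_independent), run$table1$species),
    files = stats::setNames(as.list(digests), files)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
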