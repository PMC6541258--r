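test_that("independence filter anchors on the previously retained capture", {
  caps <- make_captures("genet", "A", c("2013-06-01 10:00:00", "2013-06-01 10:30:00"))
  expect_equal(nrow(filter_independent(caps)), 1)

  caps <- make_captures("genet", "A",
                        c("2013-06-01 10:00:00", "2013-06-01 10:45:00", "2013-06-01 11:30:00"))
  kept <- filter_independent(caps)
  expect_equal(format(kept$timestamp, "%H:%M"), c("10:00", "11:30"))

  caps <- make_captures(c("genet", "civet"), "A",
                        c("2013-06-01 10:00:00", "2013-06-01 10:05:00"))
  expect_equal(nrow(filter_independent(caps)), 2)

  expect_equal(nrow(filter_independent(caps[0, ])), 0)
})

test_that("independence filter is idempotent and retained events stay spaced", {
  sv <- generate_survey(scenario_config(n_stations = 8,
                                        species = lapply(default_community(), function(s) {
                                          s$extra_visits <- 1.5
                                          s
                                        })), seed = 5)
  once <- filter_independent(sv$captures)
  twice <- filter_independent(once)
  expect_identical(as.data.frame(once), as.data.frame(twice))
  gaps <- once %>%
    dplyr::group_by(species, station_id) %>%
    dplyr::summarise(min_gap = ifelse(dplyr::n() > 1,
                                      min(diff(as.numeric(timestamp))), Inf),
                     .groups = "drop")
  expect_true(all(gaps$min_gap >= 3600))
})

test_that("elapsed time since refresh uses the most recent prior event", {
  ref <- make_refresh("A", c("2013-06-03 12:00:00", "2013-06-07 12:00:00"))
  expect_equal(elapsed_since_refresh(ts_utc("2013-06-04 06:00:00"), "A", ref), 18)
  expect_equal(elapsed_since_refresh(ts_utc("2013-06-03 12:00:00"), "A", ref), 0)
  expect_equal(elapsed_since_refresh(ts_utc("2013-06-08 12:00:00"), "A", ref), 24)
  expect_error(elapsed_since_refresh(ts_utc("2013-06-01 12:00:00"), "A", ref), "precedes")
  expect_error(elapsed_since_refresh(ts_utc("2013-06-04 06:00:00"), "ZZ", ref), "ZZ")
})

test_that("day bins are half-open 24-h intervals capped at one week", {
  expect_equal(assign_day_bin(0.5), 1L)
  expect_equal(assign_day_bin(0), 1L)
  expect_equal(assign_day_bin(24), 2L)
  expect_equal(assign_day_bin(167.9), 7L)
  expect_true(is.na(assign_day_bin(168)))
  expect_equal(assign_day_bin(c(12, 200)), c(1L, NA))
})

test_that("detection matrix counts distinct station-date detections once", {
  dep <- make_deployments(c("A", "B"), "2013-06-01", "2013-06-10",
                          inactive = list(NULL, as.Date("2013-06-04")))
  empty <- build_detection_matrix(make_captures(character(0), character(0), character(0)),
                                  dep, "genet")
  expect_equal(sum(empty$y, na.rm = TRUE), 0)
  expect_true(is.na(empty$y["B", "2013-06-04"]))
  expect_equal(sum(is.na(empty$y)), 1)

  caps <- make_captures("genet", "A", c("2013-06-02 01:00:00", "2013-06-02 23:00:00"))
  dm <- build_detection_matrix(caps, dep, "genet")
  expect_equal(sum(dm$y, na.rm = TRUE), 1)
  expect_equal(dm$y["A", "2013-06-02"], 1L)
})

test_that("detection matrix cell sum matches an independent recount on a survey", {
  sv <- generate_survey(scenario_config(n_stations = 10), seed = 3)
  ind <- filter_independent(sv$captures)
  for (sp in unique(ind$species)) {
    dm <- build_detection_matrix(ind, sv$deployments, sp)
    recount <- ind %>%
      dplyr::filter(species == sp) %>%
      dplyr::distinct(station_id, date = as.Date(timestamp)) %>%
      nrow()
    expect_equal(sum(dm$y, na.rm = TRUE), recount)
  }
})

test_that("covariate matrices follow refresh resets and effective activity", {
  dep <- make_deployments("A", "2013-06-01", "2013-06-10")
  ref <- make_refresh("A", c("2013-06-01 00:00:00", "2013-06-08 12:00:00"))
  age <- build_covariate_matrix("attractant_age", dep, ref)
  expect_equal(unname(age$x[1, ]), c(0, 1, 2, 3, 4, 5, 6, 0, 1, 2))

  inc <- build_covariate_matrix("incremental_effort", dep)
  expect_equal(unname(inc$x[1, ]), 1:10)
  tot <- build_covariate_matrix("total_effort", dep)
  expect_equal(unname(tot$x[1, ]), rep(10, 10))

  dep2 <- make_deployments("A", "2013-06-01", "2013-06-10",
                           inactive = list(as.Date(c("2013-06-03", "2013-06-07"))))
  inc2 <- build_covariate_matrix("incremental_effort", dep2)
  expect_equal(max(inc2$x, na.rm = TRUE), 8)
  expect_true(is.na(inc2$x[1, 3]))
  tot2 <- build_covariate_matrix("total_effort", dep2)
  expect_equal(unique(tot2$x[1, !is.na(tot2$x[1, ])]), 8)
})

test_that("attractant age never exceeds days since installation and is 0 on refresh dates", {
  sv <- generate_survey(scenario_config(n_stations = 12), seed = 9)
  age <- build_covariate_matrix("attractant_age", sv$deployments, sv$refresh_log)
  grid <- occasion_grid(sv$deployments)
  since_start <- outer(as.numeric(sv$deployments$start_date), as.numeric(grid$dates),
                       function(s, d) d - s)
  expect_true(all(age$x <= since_start, na.rm = TRUE))
  ref_dates <- unique(dplyr::mutate(sv$refresh_log, date = as.Date(timestamp))[c("station_id", "date")])
  for (k in seq_len(nrow(ref_dates))) {
    i <- match(ref_dates$station_id[k], age$station_ids)
    j <- match(ref_dates$date[k], age$dates)
    if (!is.na(age$x[i, j])) expect_equal(age$x[i, j], 0)
  }
})

test_that("capture rate is linear in captures and inverse in effort", {
  expect_equal(capture_rate(0, 100), 0)
  expect_equal(capture_rate(38, 301), 100 * 38 / 301)
  expect_equal(capture_rate(2 * 38, 301), 2 * capture_rate(38, 301))
  expect_equal(capture_rate(38, 2 * 301), capture_rate(38, 301) / 2)
  expect_error(capture_rate(1, 0))
})

test_that("naive summaries are simple fractions of stations and occasions", {
  dep <- make_deployments(c("A", "B", "C"), "2013-06-01", "2013-06-10")
  none <- build_detection_matrix(make_captures(character(0), character(0), character(0)),
                                 dep, "genet")
  expect_equal(naive_summaries(none)$naive_occupancy, 0)
  expect_equal(naive_summaries(none)$naive_detection, 0)

  caps <- make_captures("genet", c("A", "B"),
                        c("2013-06-02 10:00:00", "2013-06-05 11:00:00"))
  nv <- naive_summaries(build_detection_matrix(caps, dep, "genet"))
  expect_equal(nv$naive_occupancy, 2 / 3)
  expect_equal(nv$naive_detection, 2 / 30)
})
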