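test_that("likelihood matches closed forms for one-site histories", {
  # history (1) at psi = p = 0.5: -log(0.25)
  expect_equal(occu_negloglik(c(0, 0), matrix(1, 1, 1)), -log(0.25), tolerance = 1e-12)
  # history (0,0) at psi = p = 0.5: -log(0.5 * 0.25 + 0.5)
  expect_equal(occu_negloglik(c(0, 0), matrix(0, 1, 2)), -log(0.625), tolerance = 1e-12)
})

test_that("likelihood equals the enumeration oracle on random instances", {
  for (s in 1:20) {
    withr::with_seed(100 + s, {
      y <- matrix(rbinom(12, 1, 0.4), nrow = 3)
      y[sample(12, 2)] <- NA
      X <- list(matrix(rnorm(12), nrow = 3))
      par <- rnorm(3, sd = 0.8)
    })
    expect_equal(occu_negloglik(par, y, X),
                 oracle_negloglik(par[1], par[2:3], y, X),
                 tolerance = 1e-10)
  }
})

test_that("analytic gradient matches central differences", {
  withr::with_seed(7, {
    y <- matrix(rbinom(40, 1, 0.3), nrow = 8)
    y[sample(40, 5)] <- NA
    X <- list(matrix(rnorm(40), nrow = 8), matrix(rnorm(40), nrow = 8))
    par <- rnorm(4, sd = 0.5)
  })
  pre <- lurefx:::occu_prepare(y, X)
  g <- lurefx:::occu_grad_core(par, pre)
  h <- 1e-6
  g_num <- vapply(seq_along(par), function(k) {
    e <- replace(rep(0, length(par)), k, h)
    (lurefx:::occu_nll_core(par + e, pre) - lurefx:::occu_nll_core(par - e, pre)) / (2 * h)
  }, numeric(1))
  expect_equal(g, g_num, tolerance = 1e-5)
})

test_that("AICc arithmetic and its guard rails", {
  expect_equal(aicc(-10, 2, 20), 24 + 12 / 17, tolerance = 1e-12)
  expect_error(aicc(-10, 2, 3), "AICc")
  # the small-sample correction is strictly positive
  expect_gt(aicc(-10, 2, 20), -2 * (-10) + 2 * 2)
})

test_that("adding a covariate never decreases the maximized log-likelihood", {
  cfg <- recovery_config(n_stations = 60, days = 40, psi = 0.6, p0 = 0.2,
                         beta_attract = -0.1)
  sv <- generate_survey(cfg, seed = 21)
  ind <- filter_independent(sv$captures)
  dm <- build_detection_matrix(ind, sv$deployments, "focal")
  covs <- list(
    attractant_age = build_covariate_matrix("attractant_age", sv$deployments, sv$refresh_log),
    total_effort = build_covariate_matrix("total_effort", sv$deployments),
    incremental_effort = build_covariate_matrix("incremental_effort", sv$deployments)
  )
  f0 <- fit_occupancy(dm, covs, character(0))
  f1 <- fit_occupancy(dm, covs, "attractant_age")
  f2 <- fit_occupancy(dm, covs, c("attractant_age", "total_effort"))
  expect_gte(f1$loglik, f0$loglik - 1e-6)
  expect_gte(f2$loglik, f1$loglik - 1e-6)
})

test_that("station relabeling leaves the fit unchanged", {
  cfg <- recovery_config(n_stations = 40, days = 30, psi = 0.5, p0 = 0.25,
                         beta_attract = -0.15)
  sv <- generate_survey(cfg, seed = 33)
  ind <- filter_independent(sv$captures)
  dm <- build_detection_matrix(ind, sv$deployments, "focal")
  covs <- list(attractant_age = build_covariate_matrix("attractant_age",
                                                       sv$deployments, sv$refresh_log))
  fit <- fit_occupancy(dm, covs, "attractant_age")
  perm <- withr::with_seed(1, sample(nrow(dm$y)))
  dm2 <- dm
  dm2$y <- dm$y[perm, ]
  dm2$station_ids <- dm$station_ids[perm]
  covs2 <- covs
  covs2$attractant_age$x <- covs$attractant_age$x[perm, ]
  fit2 <- fit_occupancy(dm2, covs2, "attractant_age")
  expect_equal(fit$loglik, fit2$loglik, tolerance = 1e-8)
  expect_equal(fit$coef, fit2$coef, tolerance = 1e-5)
})

test_that("degenerate detection histories are flagged, not silently fitted", {
  dep <- make_deployments(sprintf("S%02d", 1:12), "2013-06-01", "2013-06-20")
  all_zero <- build_detection_matrix(make_captures(character(0), character(0), character(0)),
                                     dep, "ghost")
  expect_warning(f0 <- fit_occupancy(all_zero), "identifiable")
  expect_false(f0$converged)

  all_one <- all_zero
  all_one$species <- "ubiquitous"
  all_one$y[] <- 1L
  expect_warning(f1 <- fit_occupancy(all_one), "boundary")
  expect_true(f1$boundary)
  expect_gt(plogis(f1$coef[1]), 0.99)
  expect_gt(plogis(f1$coef[2]), 0.99)
})

test_that("constant-detection truth is recovered within 3 SE at scale", {
  withr::with_seed(55, {
    y <- matrix(rbinom(500 * 20, 1, 0.3), nrow = 500)
    occ <- rbinom(500, 1, 0.6)
    y <- y * occ
  })
  dm <- structure(list(species = "sim", y = y,
                       station_ids = sprintf("S%03d", 1:500),
                       dates = as.Date("2013-06-01") + 0:19),
                  class = "detection_matrix")
  fit <- fit_occupancy(dm)
  expect_true(fit$converged)
  expect_lt(abs(fit$coef[1] - qlogis(0.6)), 3 * fit$se[1])
  expect_lt(abs(fit$coef[2] - qlogis(0.3)), 3 * fit$se[2])
})

test_that("model set has six ranked rows with the best at delta zero", {
  cfg <- recovery_config(n_stations = 40, days = 40, psi = 0.6, p0 = 0.25,
                         beta_attract = -0.25)
  sv <- generate_survey(cfg, seed = 44)
  ind <- filter_independent(sv$captures)
  dm <- build_detection_matrix(ind, sv$deployments, "focal")
  covs <- list(
    attractant_age = build_covariate_matrix("attractant_age", sv$deployments, sv$refresh_log),
    total_effort = build_covariate_matrix("total_effort", sv$deployments),
    incremental_effort = build_covariate_matrix("incremental_effort", sv$deployments)
  )
  tab <- run_model_set(dm, covs, occu_control(n_starts = 2))
  expect_equal(nrow(tab), 6)
  expect_equal(tab$dAICc[1], 0)
  expect_false(is.unsorted(tab$AICc))
  expect_equal(sum(tab$weight), 1, tolerance = 1e-9)
  expect_equal(sort(vapply(tab$terms, length, integer(1))), c(0, 1, 1, 1, 2, 2))
})

test_that("detection predictions are logistic in the linear predictor", {
  cfg <- recovery_config(n_stations = 60, days = 40, psi = 0.6, p0 = 0.25,
                         beta_attract = -0.2)
  fit <- fit_focal_replicate(cfg, seed = 66)
  pr <- predict_detection(fit, tibble::tibble(attractant_age = 0:10))
  expect_equal(pr$p_hat[1], unname(plogis(fit$coef[2])), tolerance = 1e-10)
  expect_true(all(diff(pr$p_hat) < 0))  # negative coefficient: monotone decay
  expect_true(all(pr$lo <= pr$p_hat & pr$p_hat <= pr$hi))
  expect_error(predict_detection(fit, tibble::tibble(wrong = 1)), "column")
})

test_that("delta-method intervals agree with a parametric bootstrap", {
  cfg <- recovery_config(n_stations = 150, days = 50, psi = 0.6, p0 = 0.25,
                         beta_attract = -0.15)
  fit <- fit_focal_replicate(cfg, seed = 77)
  grid <- tibble::tibble(attractant_age = c(0, 3, 7))
  pr <- predict_detection(fit, grid)
  idx <- 2:3
  V <- fit$vcov[idx, idx]
  L <- t(chol(V))
  boot <- withr::with_seed(8, {
    draws <- replicate(4000, fit$coef[idx] + L %*% rnorm(2))
    apply(draws, 3, function(b) plogis(cbind(1, grid$attractant_age) %*% b))
  })
  lo_b <- apply(boot, 1, stats::quantile, 0.025)
  hi_b <- apply(boot, 1, stats::quantile, 0.975)
  expect_lt(max(abs(pr$lo - lo_b)), 0.02)
  expect_lt(max(abs(pr$hi - hi_b)), 0.02)
})
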