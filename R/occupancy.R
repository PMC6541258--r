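#' Negative log-likelihood of the single-season occupancy model
#'
#' The zero-inflated detection-history likelihood with constant occupancy
#' \eqn{\psi} and occasion-level detection \eqn{p_{ij}}:
#' \deqn{L = \prod_i \left[ \psi \prod_j p_{ij}^{y_{ij}} (1-p_{ij})^{1-y_{ij}}
#'       + (1-\psi)\, I\{\mathrm{all}\ y_{ij}=0\} \right]}
#' with \eqn{\mathrm{logit}(\psi) = \beta_\psi} and
#' \eqn{\mathrm{logit}(p_{ij}) = \beta_0 + \sum_t \beta_t x_{tij}}.
#' Products run over non-missing occasions only; missing occasions
#' contribute nothing.
#'
#' @param par Parameter vector `c(beta_psi, beta_p0, beta_terms...)` on
#'   the logit scale (same scale as the supplied covariates).
#' @param y Detection matrix (0/1/NA), stations by occasions.
#' @param X List (possibly empty) of covariate matrices aligned with `y`.
#' @return The negative log-likelihood (scalar).
#' @export
occu_negloglik <- function(par, y, X = list()) {
  pre <- occu_prepare(y, X)
  occu_nll_core(par, pre)
}

# shared precomputation for likelihood/gradient
occu_prepare <- function(y, X) {
  obs <- !is.na(y)
  y0 <- ifelse(obs, y, 0)
  X0 <- lapply(X, function(x) {
    if (any(!is.finite(x[obs]))) abort("non-finite covariate value in a non-missing cell")
    ifelse(obs, x, 0)
  })
  list(obs = obs * 1, y0 = y0, X0 = X0,
       never = as.numeric(rowSums(y0) == 0))
}

occu_eta <- function(par, pre) {
  eta <- matrix(par[2], nrow(pre$y0), ncol(pre$y0))
  for (t in seq_along(pre$X0)) eta <- eta + par[2 + t] * pre$X0[[t]]
  eta
}

occu_nll_core <- function(par, pre) {
  eta <- occu_eta(par, pre)
  lp <- plogis(eta, log.p = TRUE)
  lq <- plogis(-eta, log.p = TRUE)
  lcp <- rowSums(pre$obs * (pre$y0 * lp + (1 - pre$y0) * lq))
  psi <- plogis(par[1])
  L <- psi * exp(lcp) + (1 - psi) * pre$never
  -sum(log(L))
}

occu_grad_core <- function(par, pre) {
  eta <- occu_eta(par, pre)
  p <- plogis(eta)
  lp <- plogis(eta, log.p = TRUE)
  lq <- plogis(-eta, log.p = TRUE)
  lcp <- rowSums(pre$obs * (pre$y0 * lp + (1 - pre$y0) * lq))
  cp <- exp(lcp)
  psi <- plogis(par[1])
  L <- psi * cp + (1 - psi) * pre$never
  w <- psi * cp / L
  R <- pre$obs * (pre$y0 - p)
  g <- numeric(length(par))
  g[1] <- -sum((cp - pre$never) * psi * (1 - psi) / L)
  g[2] <- -sum(w * rowSums(R))
  for (t in seq_along(pre$X0)) g[2 + t] <- -sum(w * rowSums(R * pre$X0[[t]]))
  g
}

#' Optimizer settings for occupancy fits
#'
#' @param n_starts Number of deterministic starting points (the origin
#'   plus fixed perturbation patterns) guarding against local optima.
#' @param maxit Maximum BFGS iterations per start.
#' @param reltol Relative convergence tolerance passed to [stats::optim()].
#' @param grad_tol Gradient max-norm below which a solution is declared
#'   converged.
#' @param standardize Z-score detection covariates internally for
#'   conditioning; coefficients are reported back on the natural scale.
#' @return A list of settings.
#' @export
occu_control <- function(n_starts = 5, maxit = 500, reltol = 1e-12,
                         grad_tol = 1e-4, standardize = TRUE) {
  list(n_starts = n_starts, maxit = maxit, reltol = reltol,
       grad_tol = grad_tol, standardize = standardize)
}

#' Fit a single-season occupancy model with detection covariates
#'
#' Maximizes [occu_negloglik()] by BFGS with analytic gradient from
#' multiple deterministic starts. Occupancy is constant (intercept only);
#' detection is a logit-linear function of the requested covariates.
#' Standard errors come from the inverse numerical Hessian (central
#' differences of the analytic gradient); with internally standardized
#' covariates, estimates and the covariance matrix are transformed back
#' to the natural covariate scale.
#'
#' @param detection_matrix A [build_detection_matrix()] result.
#' @param covariates Named list of [build_covariate_matrix()] results (or
#'   plain matrices) aligned with the detection matrix.
#' @param terms Character vector of detection covariate names (subset of
#'   `names(covariates)`); empty for the constant-detection null model.
#' @param control See [occu_control()].
#' @return An object of class `occu_fit` with logit-scale coefficients,
#'   `vcov`, `se`, `loglik`, `K`, `AICc`, `n_sites`, `converged` and
#'   `boundary` flags.
#' @export
fit_occupancy <- function(detection_matrix, covariates = list(), terms = character(0),
                          control = occu_control()) {
  y <- detection_matrix$y
  n_sites <- nrow(y)
  terms <- as.character(terms)
  if (length(terms) > 0 && !all(terms %in% names(covariates))) {
    abort("every model term must name an entry of `covariates`")
  }
  Xnat <- lapply(covariates[terms], function(cm) if (inherits(cm, "covariate_matrix")) cm$x else cm)
  par_names <- c("psi_(Intercept)", "p_(Intercept)", if (length(terms)) paste0("p_", terms))
  K <- 2L + length(terms)

  if (sum(y, na.rm = TRUE) == 0) {
    warn(sprintf("species '%s': no detections; occupancy is not identifiable", detection_matrix$species))
    return(new_occu_fit(detection_matrix$species, terms, par_names,
                        coef = stats::setNames(rep(NA_real_, K), par_names),
                        vcov = matrix(NA_real_, K, K), loglik = NA_real_, K = K,
                        n_sites = n_sites, converged = FALSE, boundary = FALSE))
  }

  obs <- !is.na(y)
  centers <- scales <- stats::setNames(rep(0, length(terms)), terms)
  Xfit <- Xnat
  if (isTRUE(control$standardize) && length(terms) > 0) {
    for (t in terms) {
      v <- Xnat[[t]][obs]
      m <- mean(v); s <- stats::sd(v)
      if (!is.finite(s) || s == 0) { m <- 0; s <- 1 }
      centers[t] <- m; scales[t] <- s
      Xfit[[t]] <- (Xnat[[t]] - m) / s
    }
  } else {
    scales[] <- 1
  }
  pre <- occu_prepare(y, Xfit)

  starts <- start_matrix(K, control$n_starts)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    opt <- tryCatch(
      optim(starts[s, ], fn = occu_nll_core, gr = occu_grad_core, pre = pre,
            method = "BFGS",
            control = list(maxit = control$maxit, reltol = control$reltol)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-9) best <- opt
  }
  if (is.null(best)) abort("occupancy optimization failed from every start")

  # Newton polish: BFGS can stop with a slightly loose gradient; a few
  # damped Newton steps tighten it to the declared tolerance
  grad <- occu_grad_core(best$par, pre)
  H <- hessian_from_grad(best$par, pre)
  for (it in 1:10) {
    if (max(abs(grad)) < control$grad_tol) break
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    cand <- best$par - step
    val <- occu_nll_core(cand, pre)
    if (!is.finite(val) || val > best$value + 1e-8) break
    best$par <- cand
    best$value <- val
    grad <- occu_grad_core(best$par, pre)
    H <- hessian_from_grad(best$par, pre)
  }
  V_std <- tryCatch(solve(H), error = function(e) matrix(NA_real_, K, K))
  boundary <- any(abs(best$par) > 8)
  converged <- best$convergence == 0 && max(abs(grad)) < control$grad_tol &&
    all(is.finite(V_std)) && all(diag(V_std) > 0)
  if (boundary) {
    warn(sprintf("fit for '%s' [%s] is at or near a parameter boundary",
                 detection_matrix$species,
                 if (length(terms)) paste(terms, collapse = "+") else "."))
  }

  # back-transform (b0 absorbs -sum b_t m_t / s_t; slopes divide by s_t)
  A <- diag(K)
  if (length(terms) > 0) {
    for (t in seq_along(terms)) {
      A[2, 2 + t] <- -centers[t] / scales[t]
      A[2 + t, 2 + t] <- 1 / scales[t]
    }
  }
  coef_nat <- drop(A %*% best$par)
  V_nat <- A %*% V_std %*% t(A)
  names(coef_nat) <- par_names
  dimnames(V_nat) <- list(par_names, par_names)

  new_occu_fit(detection_matrix$species, terms, par_names,
               coef = coef_nat, vcov = V_nat, loglik = -best$value, K = K,
               n_sites = n_sites, converged = converged, boundary = boundary)
}

new_occu_fit <- function(species, terms, par_names, coef, vcov, loglik, K,
                         n_sites, converged, boundary) {
  se <- sqrt(pmax(diag(vcov), 0))
  names(se) <- par_names
  aic_c <- if (is.na(loglik) || n_sites - K - 1 <= 0) NA_real_ else aicc(loglik, K, n_sites)
  structure(
    list(species = species, terms = terms, coef = coef, vcov = vcov, se = se,
         loglik = loglik, K = K, AICc = aic_c, n_sites = n_sites,
         converged = converged, boundary = boundary),
    class = "occu_fit"
  )
}

start_matrix <- function(K, n_starts) {
  patterns <- rbind(
    rep(0, K),
    c(0.5, -1, rep(0, K - 2)),
    c(-0.5, 1, rep(0, K - 2)),
    c(1, -2, rep(0.25, K - 2)),
    c(-1, 0.5, rep(-0.25, K - 2))
  )
  patterns[seq_len(min(n_starts, nrow(patterns))), , drop = FALSE]
}

hessian_from_grad <- function(par, pre, h = 1e-5) {
  K <- length(par)
  H <- matrix(0, K, K)
  for (k in seq_len(K)) {
    e <- rep(0, K); e[k] <- h
    H[, k] <- (occu_grad_core(par + e, pre) - occu_grad_core(par - e, pre)) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Akaike's information criterion corrected for small samples
#'
#' \deqn{AICc = -2\,\ell + 2K + \frac{2K(K+1)}{n - K - 1}}
#' with effective sample size `n` taken as the number of stations.
#'
#' @param loglik Maximized log-likelihood.
#' @param K Number of estimated parameters.
#' @param n Effective sample size (stations).
#' @return The AICc value.
#' @export
aicc <- function(loglik, K, n) {
  if (n - K - 1 <= 0) {
    abort(sprintf("AICc undefined: n - K - 1 = %d must be positive", n - K - 1))
  }
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Fit and rank the candidate detection-model set
#'
#' Fits the six-model set combining attractant age and the two effort
#' measures univariately and additively (effort measures are alternative
#' parameterizations of the same quantity and are never combined with
#' each other), all with constant occupancy:
#' `.`, `attractant_age`, `total_effort`, `incremental_effort`,
#' `attractant_age + total_effort`, `attractant_age + incremental_effort`.
#' Models are ranked by AICc.
#'
#' @inheritParams fit_occupancy
#' @return A tibble with one row per model (columns `model`, `K`,
#'   `loglik`, `AICc`, `dAICc`, `weight`, `converged`) and the fitted
#'   objects in a `fit` list-column.
#' @export
run_model_set <- function(detection_matrix, covariates, control = occu_control()) {
  specs <- list(
    character(0),
    "attractant_age",
    "total_effort",
    "incremental_effort",
    c("attractant_age", "total_effort"),
    c("attractant_age", "incremental_effort")
  )
  fits <- purrr::map(specs, ~ fit_occupancy(detection_matrix, covariates, .x, control))
  tab <- tibble(
    model = vapply(specs, function(s) {
      sprintf("psi(.) p(%s)", if (length(s)) paste(s, collapse = " + ") else ".")
    }, character(1)),
    terms = specs,
    K = vapply(fits, `[[`, integer(1), "K"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    AICc = vapply(fits, `[[`, numeric(1), "AICc"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    fit = fits
  )
  tab <- arrange(tab, .data$AICc)
  tab$dAICc <- tab$AICc - tab$AICc[1]
  rel <- exp(-tab$dAICc / 2)
  tab$weight <- rel / sum(rel, na.rm = TRUE)
  select(tab, "model", "terms", "K", "loglik", "AICc", "dAICc", "weight", "converged", "fit")
}

#' Predicted detection probability over a covariate grid
#'
#' Inverse-logit of the detection linear predictor with 95% Wald
#' confidence intervals computed by the delta method on the logit scale
#' and then transformed, so intervals stay inside (0, 1).
#'
#' @param fit An [fit_occupancy()] result.
#' @param newdata Tibble with one column per model term; a single
#'   intercept-only row is used when the model has no terms and `newdata`
#'   is omitted.
#' @param level Confidence level.
#' @return `newdata` with columns `p_hat`, `lo`, `hi`.
#' @export
predict_detection <- function(fit, newdata = NULL, level = 0.95) {
  if (is.null(newdata)) {
    if (length(fit$terms) > 0) abort("newdata is required when the model has covariates")
    newdata <- tibble(.rows = 1)
  }
  if (!all(fit$terms %in% names(newdata))) {
    abort("newdata must contain a column for each model term")
  }
  Xg <- cbind(1, as.matrix(newdata[fit$terms]))
  idx <- seq(2, 2 + length(fit$terms))
  b <- fit$coef[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  eta <- drop(Xg %*% b)
  se_eta <- sqrt(pmax(rowSums((Xg %*% V) * Xg), 0))
  z <- qnorm(1 - (1 - level) / 2)
  out <- as_tibble(newdata)
  out$p_hat <- plogis(eta)
  out$lo <- plogis(eta - z * se_eta)
  out$hi <- plogis(eta + z * se_eta)
  out
}

#' @export
print.occu_fit <- function(x, ...) {
  cat(sprintf("<occu_fit> %s  psi(.) p(%s)\n", x$species,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "."))
  cat(sprintf("  psi = %.3f  logLik = %.3f  K = %d  AICc = %.3f  sites = %d%s%s\n",
              plogis(x$coef[1]), x$loglik, x$K, x$AICc, x$n_sites,
              if (!x$converged) "  [not converged]" else "",
              if (x$boundary) "  [boundary]" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.occu_fit <- function(x, ...) {
  est <- x$coef
  se <- x$se
  stat <- est / se
  tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = 2 * stats::pnorm(-abs(unname(stat)))
  )
}

#' @exportS3Method generics::glance
glance.occu_fit <- function(x, ...) {
  tibble(
    psi = unname(plogis(x$coef[1])),
    logLik = x$loglik,
    K = x$K,
    AICc = x$AICc,
    n_sites = x$n_sites,
    converged = x$converged,
    boundary = x$boundary
  )
}

#' Plot a predicted detection curve
#'
#' @param fit An [fit_occupancy()] result with at least one term.
#' @param term Covariate to vary; other terms are held at `at`.
#' @param grid Values of `term` to predict at.
#' @param at Named list of fixed values for the remaining terms
#'   (default 0).
#' @return A ggplot.
#' @export
plot_detection_curve <- function(fit, term = fit$terms[1],
                                 grid = seq(0, 27, by = 0.25), at = list()) {
  nd <- tibble(!!term := grid)
  for (t in setdiff(fit$terms, term)) nd[[t]] <- if (!is.null(at[[t]])) at[[t]] else 0
  pr <- predict_detection(fit, nd)
  ggplot2::ggplot(pr, ggplot2::aes(x = .data[[term]], y = .data$p_hat)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = term, y = "Detection probability")
}
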