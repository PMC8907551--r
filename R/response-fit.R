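#' Fit the individual response model to one change-table slice
#'
#' Fits, by restricted maximum likelihood, the random-intercept/random-slope
#' model `delta_il = alpha_i + beta_i * l + eps_il` to the change values of
#' one marker x timepoint x scale, with `(alpha_i, beta_i)` bivariate normal.
#' The four quantities of interest are the mean and SD of the intercepts
#' (average response to the stress test at 100% body weight, and its
#' inter-individual variation) and the mean and SD of the slopes (average
#' dose-response per load level, and its inter-individual variation).
#'
#' Inference: Wald tests with a normal reference for the two means;
#' likelihood-ratio tests against the mixture chi-square reference
#' ([pchisq_mix()]) for the two SDs, whose null lies on the boundary of the
#' parameter space (removing a correlated random effect drops one variance
#' and one covariance, hence an equal mixture of chi-square with 1 and 2
#' degrees of freedom). The relative covariance factor is optimized on a
#' Cholesky scale with the residual variance profiled out; SD estimates
#' below 1e-8 are reported as 0 with a boundary flag. Data in which every
#' subject's points are exactly collinear (zero residual variance) are
#' detected up front and returned as an exact boundary fit rather than an
#' error.
#'
#' @param changes Change-table tibble with columns `subject_id`, `load_code`,
#'   `delta` (see [build_change_table()] or [simulate_change_values()]);
#'   optionally pre-filtered by the `marker`, `timepoint`, `scale` arguments.
#' @param marker,timepoint,scale Optional slice selectors; after selection
#'   the slice must be unique in these identifiers.
#' @param sd_ci If `TRUE`, also compute profile-likelihood CIs for the two
#'   SDs (see [ci_sd()]; costs several reduced optimizations).
#' @param level Confidence level (default 0.95).
#' @param n_restarts Maximum jittered restarts of the REML optimizer.
#' @return An object of class `response_fit`; see [tidy.response_fit()] for
#'   a tabular view. Key fields: `mu_alpha_hat`, `sd_alpha_hat`,
#'   `mu_beta_hat`, `sd_beta_hat`, `rho_hat`, `sd_error_hat`, the CIs and
#'   p-values, `converged`, and `boundary` flags for SD estimates at 0.
#' @examples
#' cfg <- sim_config(n_subjects = 24, seed = 1)
#' fit <- fit_response_model(simulate_change_values(cfg))
#' fit
#' tidy(fit)
#' @export
fit_response_model <- function(changes, marker = NULL, timepoint = NULL,
                               scale = NULL, sd_ci = FALSE, level = 0.95,
                               n_restarts = 5L) {
  slice <- slice_changes(changes, marker, timepoint, scale)
  rd <- make_reml_data(slice$subject_id, slice$load_code, slice$delta)
  check_fit_input(rd)
  fit <- if (is_exact_fit(rd)) {
    exact_boundary_fit(rd)
  } else {
    reml_response_fit(rd, n_restarts)
  }
  fit$marker <- attr(slice, "marker")
  fit$timepoint <- attr(slice, "timepoint")
  fit$scale <- attr(slice, "scale")
  fit$level <- level
  fit <- add_mean_inference(fit, level)
  fit <- add_sd_tests(fit)
  if (sd_ci) {
    fit$ci_sd_alpha <- ci_sd(fit, "alpha", level)
    fit$ci_sd_beta <- ci_sd(fit, "beta", level)
  }
  fit
}

slice_changes <- function(changes, marker, timepoint, scale) {
  need <- c("subject_id", "load_code", "delta")
  missing_cols <- setdiff(need, names(changes))
  if (length(missing_cols) > 0) {
    abort(paste0("Change table lacks column(s) ",
                 paste0("`", missing_cols, "`", collapse = ", "), "."),
          class = "mechmarker_input_error")
  }
  for (col in c("marker", "timepoint", "scale")) {
    val <- get(col)
    if (!is.null(val) && col %in% names(changes)) {
      changes <- changes[changes[[col]] == val, , drop = FALSE]
    }
  }
  out <- changes
  for (col in c("marker", "timepoint", "scale")) {
    lv <- if (col %in% names(changes)) unique(changes[[col]]) else get(col)
    if (length(lv) > 1) {
      abort(paste0("Change slice is not unique in `", col, "` (",
                   paste(lv, collapse = ", "),
                   "); select one with the `", col, "` argument."),
            class = "mechmarker_input_error")
    }
    attr(out, col) <- if (length(lv) == 1) lv else NA_character_
  }
  out
}

check_fit_input <- function(rd) {
  if (rd$n_subjects < 2) {
    abort("At least 2 subjects are required.",
          class = "mechmarker_input_error")
  }
  n_loads <- vapply(rd$patterns, function(p) length(unique(p$l)), integer(1))
  if (any(n_loads < 2)) {
    abort("Every subject needs change values at >= 2 load levels.",
          class = "mechmarker_input_error")
  }
}

# Per-subject OLS; exact collinearity of every subject's points means the
# residual variance is 0 and the REML criterion diverges.
subject_ols <- function(rd) {
  out <- list()
  for (pat in rd$patterns) {
    X <- pat$X
    XtXi <- solve(crossprod(X))
    cf <- XtXi %*% crossprod(X, pat$Y)
    res <- pat$Y - X %*% cf
    out[[length(out) + 1]] <- list(coef = cf, max_res = max(abs(res)))
  }
  list(
    alpha = unlist(lapply(out, function(o) o$coef[1, ])),
    beta = unlist(lapply(out, function(o) o$coef[2, ])),
    max_res = max(vapply(out, function(o) o$max_res, numeric(1)))
  )
}

is_exact_fit <- function(rd) {
  scale <- max(1, max(abs(unlist(lapply(rd$patterns, function(p) p$Y)))))
  subject_ols(rd)$max_res < 1e-10 * scale
}

exact_boundary_fit <- function(rd) {
  ols <- subject_ols(rd)
  n <- rd$n_subjects
  sd_a <- if (n > 1) sd(ols$alpha) else 0
  sd_b <- if (n > 1) sd(ols$beta) else 0
  if (sd_a < 1e-10) sd_a <- 0
  if (sd_b < 1e-10) sd_b <- 0
  structure(list(
    mu_alpha_hat = mean(ols$alpha), sd_alpha_hat = sd_a,
    mu_beta_hat = mean(ols$beta), sd_beta_hat = sd_b,
    rho_hat = if (sd_a > 0 && sd_b > 0) cor(ols$alpha, ols$beta) else NA_real_,
    sd_error_hat = 0,
    se_mu_alpha = sd_a / sqrt(n), se_mu_beta = sd_b / sqrt(n),
    loglik = Inf, n_subjects = n, n_obs = rd$N,
    converged = TRUE, degenerate = TRUE,
    boundary = c(sd_alpha = sd_a == 0, sd_beta = sd_b == 0, sd_error = TRUE),
    reml_data = rd
  ), class = "response_fit")
}

reml_response_fit <- function(rd, n_restarts) {
  fit <- reml_fit(rd, "both", n_restarts = n_restarts)
  if (!fit$converged || is.null(fit$details)) {
    return(structure(list(
      mu_alpha_hat = NA_real_, sd_alpha_hat = NA_real_,
      mu_beta_hat = NA_real_, sd_beta_hat = NA_real_,
      rho_hat = NA_real_, sd_error_hat = NA_real_,
      se_mu_alpha = NA_real_, se_mu_beta = NA_real_,
      loglik = NA_real_, n_subjects = rd$n_subjects, n_obs = rd$N,
      converged = FALSE, degenerate = FALSE,
      boundary = c(sd_alpha = FALSE, sd_beta = FALSE, sd_error = FALSE),
      reml_data = rd
    ), class = "response_fit"))
  }
  vc <- extract_varcomp(fit)
  sd_a <- if (vc$sd_alpha < 1e-8) 0 else vc$sd_alpha
  sd_b <- if (vc$sd_beta < 1e-8) 0 else vc$sd_beta
  structure(list(
    mu_alpha_hat = fit$details$beta[1], sd_alpha_hat = sd_a,
    mu_beta_hat = fit$details$beta[2], sd_beta_hat = sd_b,
    rho_hat = vc$rho, sd_error_hat = vc$sd_error,
    se_mu_alpha = sqrt(fit$details$cov_beta[1, 1]),
    se_mu_beta = sqrt(fit$details$cov_beta[2, 2]),
    loglik = fit$loglik, theta = fit$theta,
    n_subjects = rd$n_subjects, n_obs = rd$N,
    converged = TRUE, degenerate = FALSE,
    boundary = c(sd_alpha = sd_a == 0, sd_beta = sd_b == 0,
                 sd_error = vc$sd_error < 1e-8),
    reml_data = rd
  ), class = "response_fit")
}

add_mean_inference <- function(fit, level) {
  z <- qnorm(1 - (1 - level) / 2)
  for (w in c("alpha", "beta")) {
    est <- fit[[paste0("mu_", w, "_hat")]]
    se <- fit[[paste0("se_mu_", w)]]
    if (!fit$converged || is.na(est)) {
      ci <- c(NA_real_, NA_real_)
      p <- NA_real_
    } else if (is.na(se) || se == 0) {
      ci <- c(est, est)
      p <- if (abs(est) < 1e-12) 1 else 0
    } else {
      ci <- est + c(-1, 1) * z * se
      p <- 2 * pnorm(-abs(est / se))
    }
    fit[[paste0("ci_mu_", w)]] <- ci
    fit[[paste0("p_mu_", w)]] <- p
  }
  fit
}

add_sd_tests <- function(fit) {
  fit$p_sd_alpha <- test_sd(fit, "alpha")
  fit$p_sd_beta <- test_sd(fit, "beta")
  fit
}

#' Wald inference for a fixed-effect mean
#'
#' Two-sided Wald test of the mean intercept (average response) or mean
#' slope (average dose-response) against 0, using the REML standard error
#' and a normal reference.
#'
#' @param fit A [fit_response_model()] fit.
#' @param which `"alpha"` (response) or `"beta"` (slope).
#' @return A one-row tibble: `estimate`, `conf.low`, `conf.high`, `p.value`.
#' @examples
#' cfg <- sim_config(n_subjects = 24, seed = 1)
#' fit <- fit_response_model(simulate_change_values(cfg))
#' test_mean(fit, "beta")
#' @export
test_mean <- function(fit, which = c("alpha", "beta")) {
  which <- match.arg(which)
  stopifnot(inherits(fit, "response_fit"))
  if (!fit$converged) {
    abort("Inference unavailable: the model fit did not converge.",
          class = "mechmarker_inference_error")
  }
  ci <- fit[[paste0("ci_mu_", which)]]
  tibble(
    term = paste0("mu_", which),
    estimate = fit[[paste0("mu_", which, "_hat")]],
    conf.low = ci[1], conf.high = ci[2],
    p.value = fit[[paste0("p_mu_", which)]]
  )
}

#' Boundary likelihood-ratio test for a random-effect SD
#'
#' Tests whether the between-subject SD of the intercepts (`"alpha"`) or of
#' the slopes (`"beta"`) is zero. The reduced model removes the tested
#' random effect together with its covariance with the retained one; the
#' LRT statistic (twice the REML log-likelihood difference, clipped at 0)
#' is referred to the 50:50 mixture of chi-square distributions with 1 and
#' 2 degrees of freedom (with 0 and 1 when the model holds a single random
#' effect).
#'
#' @inheritParams test_mean
#' @return The mixture chi-square p-value.
#' @examples
#' cfg <- sim_config(n_subjects = 24, seed = 1)
#' fit <- fit_response_model(simulate_change_values(cfg))
#' test_sd(fit, "beta")
#' @export
test_sd <- function(fit, which = c("alpha", "beta")) {
  which <- match.arg(which)
  stopifnot(inherits(fit, "response_fit"))
  if (!fit$converged) {
    abort("Inference unavailable: the model fit did not converge.",
          class = "mechmarker_inference_error")
  }
  if (isTRUE(fit$degenerate)) {
    est <- fit[[paste0("sd_", which, "_hat")]]
    return(if (est > 0) 0 else 1)
  }
  reduced <- reml_fit(fit$reml_data, if (which == "alpha") "slope" else "intercept")
  if (!reduced$converged) {
    abort("Inference unavailable: the reduced model did not converge.",
          class = "mechmarker_inference_error")
  }
  stat <- max(0, 2 * (fit$loglik - reduced$loglik))
  pchisq_mix(stat, dfs = c(1, 2))
}

#' Profile-likelihood confidence interval for a random-effect SD
#'
#' Inverts the mixture chi-square likelihood-ratio test: the interval holds
#' all SD values whose profiled REML log-likelihood (remaining variance
#' parameters re-optimized) stays within the mixture critical value of the
#' maximum. The lower bound is clipped at 0; the upper bound is `Inf` when
#' the profile never drops below the threshold.
#'
#' @inheritParams test_mean
#' @param level Confidence level.
#' @return Numeric vector `c(lower, upper)` on the SD scale.
#' @examples
#' cfg <- sim_config(n_subjects = 24, seed = 1)
#' fit <- fit_response_model(simulate_change_values(cfg))
#' ci_sd(fit, "alpha")
#' @export
ci_sd <- function(fit, which = c("alpha", "beta"), level = 0.95) {
  which <- match.arg(which)
  stopifnot(inherits(fit, "response_fit"))
  if (!fit$converged) {
    abort("Inference unavailable: the model fit did not converge.",
          class = "mechmarker_inference_error")
  }
  est <- fit[[paste0("sd_", which, "_hat")]]
  if (isTRUE(fit$degenerate)) {
    return(if (est > 0) c(est, est) else c(0, Inf))
  }
  rd <- fit$reml_data
  qcrit <- qchisq_mix(1 - level, dfs = c(1, 2))
  lp <- function(s) profile_sd_loglik(rd, fit, which, s)
  gap <- function(s) 2 * (fit$loglik - lp(s)) - qcrit

  scale_ref <- max(est, fit$sd_error_hat, 1e-3)
  lower <- if (gap(0) <= 0) {
    0
  } else {
    lo_start <- max(est, 1e-6 * scale_ref)
    tryCatch(uniroot(gap, c(1e-8 * scale_ref, lo_start), tol = 1e-4 * scale_ref)$root,
             error = function(e) 0)
  }
  upper <- Inf
  s_lo <- max(est, 1e-6 * scale_ref)
  g_lo <- gap(s_lo)
  for (mult in 2^(1:14)) {
    s_hi <- scale_ref * mult
    if (s_hi <= s_lo) next
    g_hi <- gap(s_hi)
    if (is.finite(g_hi) && g_hi > 0) {
      upper <- uniroot(function(s) gap(s), c(s_lo, s_hi),
                       f.lower = g_lo, f.upper = g_hi,
                       tol = 1e-4 * scale_ref)$root
      break
    }
    s_lo <- s_hi
    g_lo <- g_hi
  }
  c(max(0, lower), upper)
}

# REML log-likelihood with one random-effect SD fixed at `s`, the other
# variance parameters (other SD, correlation, residual SD) re-optimized.
profile_sd_loglik <- function(rd, fit, which, s) {
  start_other <- if (which == "alpha") fit$sd_beta_hat else fit$sd_alpha_hat
  if (start_other <= 0) start_other <- 0.3 * max(fit$sd_error_hat, 1e-3)
  start_rho <- if (is.na(fit$rho_hat)) 0 else max(-0.9, min(0.9, fit$rho_hat))
  start_se <- max(fit$sd_error_hat, 1e-3)
  obj <- function(par) {
    sd_other <- par[1]
    rho <- par[2]
    sd_e <- par[3]
    G <- if (which == "alpha") {
      matrix(c(s^2, s * sd_other * rho, s * sd_other * rho, sd_other^2), 2, 2)
    } else {
      matrix(c(sd_other^2, s * sd_other * rho, s * sd_other * rho, s^2), 2, 2)
    }
    v <- reml_direct(rd, G, sd_e^2)
    if (!is.finite(v)) return(1e12)
    -v
  }
  best <- Inf
  for (st in list(c(start_other, start_rho, start_se),
                  c(0.5 * start_se, 0, start_se))) {
    res <- tryCatch(
      nlminb(st, obj, lower = c(0, -0.999, 1e-8), upper = c(1e6, 0.999, 1e6),
             control = list(rel.tol = 1e-9, iter.max = 400L)),
      error = function(e) NULL
    )
    if (!is.null(res) && res$objective < best) best <- res$objective
  }
  -best
}

#' @export
print.response_fit <- function(x, ...) {
  cat("<response_fit>",
      if (!is.na(x$marker %||% NA)) paste0(" ", x$marker) else "",
      if (!is.na(x$timepoint %||% NA)) paste0(" @ ", x$timepoint) else "",
      if (!is.na(x$scale %||% NA)) paste0(" [", x$scale, " scale]") else "",
      "\n", sep = "")
  cat(sprintf("  %d subjects, %d observations; converged: %s%s\n",
              x$n_subjects, x$n_obs, x$converged,
              if (any(x$boundary)) paste0(" (boundary: ",
                paste(names(x$boundary)[x$boundary], collapse = ", "), ")")
              else ""))
  if (x$converged) {
    cat(sprintf("  response  mean %.2f [%.2f; %.2f] p=%.4g | SD %.2f p=%.4g\n",
                x$mu_alpha_hat, x$ci_mu_alpha[1], x$ci_mu_alpha[2],
                x$p_mu_alpha, x$sd_alpha_hat, x$p_sd_alpha))
    cat(sprintf("  slope     mean %.2f [%.2f; %.2f] p=%.4g | SD %.2f p=%.4g\n",
                x$mu_beta_hat, x$ci_mu_beta[1], x$ci_mu_beta[2],
                x$p_mu_beta, x$sd_beta_hat, x$p_sd_beta))
    cat(sprintf("  residual SD %.2f; random-effect correlation %s\n",
                x$sd_error_hat,
                if (is.na(x$rho_hat)) "undefined" else sprintf("%.2f", x$rho_hat)))
  }
  invisible(x)
}

#' Tidy a response-model fit
#'
#' @param x A `response_fit`.
#' @param ... Unused.
#' @return One row per model quantity (`mu_alpha`, `sd_alpha`, `mu_beta`,
#'   `sd_beta`, `sd_error`, `rho`): estimate, confidence bounds (where
#'   available) and p-value.
#' @export
tidy.response_fit <- function(x, ...) {
  ci_sa <- x$ci_sd_alpha %||% c(NA_real_, NA_real_)
  ci_sb <- x$ci_sd_beta %||% c(NA_real_, NA_real_)
  tibble(
    term = c("mu_alpha", "sd_alpha", "mu_beta", "sd_beta", "sd_error", "rho"),
    estimate = c(x$mu_alpha_hat, x$sd_alpha_hat, x$mu_beta_hat,
                 x$sd_beta_hat, x$sd_error_hat, x$rho_hat),
    conf.low = c(x$ci_mu_alpha[1], ci_sa[1], x$ci_mu_beta[1], ci_sb[1],
                 NA, NA),
    conf.high = c(x$ci_mu_alpha[2], ci_sa[2], x$ci_mu_beta[2], ci_sb[2],
                  NA, NA),
    p.value = c(x$p_mu_alpha, x$p_sd_alpha, x$p_mu_beta, x$p_sd_beta, NA, NA)
  )
}

#' Glance at a response-model fit
#'
#' @param x A `response_fit`.
#' @param ... Unused.
#' @return A one-row tibble with sample sizes, the REML log-likelihood and
#'   convergence/boundary indicators.
#' @export
glance.response_fit <- function(x, ...) {
  tibble(
    n_subjects = x$n_subjects, n_obs = x$n_obs, logLik = x$loglik,
    converged = x$converged, degenerate = isTRUE(x$degenerate),
    boundary_sd_alpha = unname(x$boundary["sd_alpha"]),
    boundary_sd_beta = unname(x$boundary["sd_beta"])
  )
}

#' Fit the response model across all marker x timepoint slices
#'
#' Maps [fit_response_model()] over every marker x timepoint x scale slice
#' of a change table and collects the estimates in the layout of the
#' published response tables (mean and SD with CI and p-value per slice).
#'
#' @param changes Change-table tibble (may hold several markers, timepoints
#'   and scales).
#' @param sd_ci Compute profile CIs for the SDs (slower).
#' @return A `response_table` tibble, one row per slice, with a `fit`
#'   list-column holding the underlying `response_fit` objects.
#' @examples
#' cfg <- sim_config(n_subjects = 8, seed = 3)
#' panel <- average_duplicates(simulate_concentration_panel(cfg))
#' changes <- build_change_table(panel, "relative", markers = "COMP")
#' fit_response_models(changes)
#' @export
fit_response_models <- function(changes, sd_ci = FALSE) {
  slices <- changes %>%
    distinct(.data$marker, .data$timepoint, .data$scale) %>%
    arrange(match(.data$marker, marker_levels()),
            match(.data$timepoint, timepoint_levels()))
  rows <- purrr::pmap(slices, function(marker, timepoint, scale) {
    fit <- fit_response_model(changes, marker = marker,
                              timepoint = timepoint, scale = scale,
                              sd_ci = sd_ci)
    ci_sa <- fit$ci_sd_alpha %||% c(NA_real_, NA_real_)
    ci_sb <- fit$ci_sd_beta %||% c(NA_real_, NA_real_)
    tibble(
      marker = marker, timepoint = timepoint, scale = scale,
      mu_alpha = fit$mu_alpha_hat,
      mu_alpha_low = fit$ci_mu_alpha[1], mu_alpha_high = fit$ci_mu_alpha[2],
      p_mu_alpha = fit$p_mu_alpha,
      sd_alpha = fit$sd_alpha_hat,
      sd_alpha_low = ci_sa[1], sd_alpha_high = ci_sa[2],
      p_sd_alpha = fit$p_sd_alpha,
      mu_beta = fit$mu_beta_hat,
      mu_beta_low = fit$ci_mu_beta[1], mu_beta_high = fit$ci_mu_beta[2],
      p_mu_beta = fit$p_mu_beta,
      sd_beta = fit$sd_beta_hat,
      sd_beta_low = ci_sb[1], sd_beta_high = ci_sb[2],
      p_sd_beta = fit$p_sd_beta,
      rho = fit$rho_hat, sd_error = fit$sd_error_hat,
      n_subjects = fit$n_subjects, converged = fit$converged,
      fit = list(fit)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("response_table", class(out))
  out
}
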