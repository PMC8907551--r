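# Restricted maximum likelihood engine for the individual response model
#
#   delta_il = alpha_i + beta_i * l + eps_il
#
# with (alpha_i, beta_i) bivariate normal and i.i.d. normal residuals.
# The residual variance is profiled out analytically: with the relative
# covariance factor Lambda (lower-triangular, log-Cholesky-style
# parameterization theta), the marginal covariance per subject is
# sigma^2 * W_i(theta), W_i = I + Z_i Lambda Lambda' Z_i', and the REML
# criterion reduces to a function of theta alone. Subjects sharing a load
# pattern share W_i, so balanced designs cost one small linear solve per
# criterion evaluation.

# Group subjects by identical load patterns for fast likelihood evaluation.
make_reml_data <- function(subject_id, load_code, delta) {
  ok <- complete.cases(subject_id, load_code, delta)
  subject_id <- subject_id[ok]
  load_code <- load_code[ok]
  delta <- delta[ok]
  split_loads <- split(load_code, subject_id)
  split_y <- split(delta, subject_id)
  # order within subject by load for pattern matching
  patterns <- list()
  for (s in names(split_loads)) {
    o <- order(split_loads[[s]])
    l <- split_loads[[s]][o]
    y <- split_y[[s]][o]
    key <- paste(l, collapse = ",")
    if (is.null(patterns[[key]])) {
      patterns[[key]] <- list(l = l, Y = matrix(y, ncol = 1))
    } else {
      patterns[[key]]$Y <- cbind(patterns[[key]]$Y, y)
    }
  }
  patterns <- lapply(patterns, function(p) {
    p$X <- cbind(1, p$l)
    p$n_g <- ncol(p$Y)
    p
  })
  list(
    patterns = patterns,
    N = length(delta),
    p = 2L,
    n_subjects = length(split_loads),
    subject_ids = names(split_loads)
  )
}

z_columns <- function(random) {
  switch(random,
    both = 1:2,
    intercept = 1L,
    slope = 2L,
    none = integer(0),
    abort(paste0("Unknown random structure `", random, "`."))
  )
}

n_theta <- function(random) {
  switch(random, both = 3L, intercept = 1L, slope = 1L, none = 0L)
}

lambda_matrix <- function(theta, random) {
  switch(random,
    both = matrix(c(theta[1], theta[2], 0, theta[3]), 2, 2),
    intercept = matrix(theta[1], 1, 1),
    slope = matrix(theta[1], 1, 1),
    none = NULL
  )
}

# Profiled REML log-likelihood; optionally returns the GLS solution.
reml_profiled <- function(rd, theta, random, details = FALSE) {
  zc <- z_columns(random)
  lam <- lambda_matrix(theta, random)
  p <- rd$p
  A <- matrix(0, p, p)
  b <- numeric(p)
  qsum <- 0
  logdetW <- 0
  for (pat in rd$patterns) {
    X <- pat$X
    k <- nrow(X)
    W <- diag(k)
    if (length(zc) > 0) {
      Z <- X[, zc, drop = FALSE]
      G <- lam %*% t(lam)
      W <- W + Z %*% G %*% t(Z)
    }
    ch <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(ch)) {
      return(if (details) NULL else -Inf)
    }
    logdetW <- logdetW + 2 * sum(log(diag(ch))) * pat$n_g
    Wi_X <- backsolve(ch, forwardsolve(t(ch), X))
    Wi_Y <- backsolve(ch, forwardsolve(t(ch), pat$Y))
    A <- A + pat$n_g * crossprod(X, Wi_X)
    b <- b + crossprod(X, rowSums(Wi_Y))[, 1]
    qsum <- qsum + sum(pat$Y * Wi_Y)
  }
  chA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(chA)) {
    return(if (details) NULL else -Inf)
  }
  beta <- backsolve(chA, forwardsolve(t(chA), b))
  rss <- qsum - sum(beta * b)
  nu <- rd$N - p
  if (rss <= 0) {
    # data exactly interpolated at this theta: criterion diverges
    return(if (details) {
      list(loglik = Inf, beta = beta, sigma2 = 0,
           cov_beta = matrix(0, p, p), logdetW = logdetW)
    } else {
      Inf
    })
  }
  sigma2 <- rss / nu
  loglik <- -0.5 * (nu * (log(2 * pi) + 1) + nu * log(sigma2) +
                      logdetW + 2 * sum(log(diag(chA))))
  if (!details) {
    return(loglik)
  }
  cov_beta <- sigma2 * chol2inv(chA)
  list(loglik = loglik, beta = beta, sigma2 = sigma2, cov_beta = cov_beta,
       logdetW = logdetW)
}

# Direct REML log-likelihood for an explicit random-effects covariance G
# (on the variance scale) and residual variance sig2e. Used for profiling
# one SD at a fixed value, where the residual variance can no longer be
# profiled out against it.
reml_direct <- function(rd, G, sig2e, random = "both") {
  zc <- z_columns(random)
  p <- rd$p
  if (sig2e <= 0) sig2e <- 1e-12
  A <- matrix(0, p, p)
  b <- numeric(p)
  qsum <- 0
  logdetV <- 0
  for (pat in rd$patterns) {
    X <- pat$X
    k <- nrow(X)
    V <- sig2e * diag(k)
    if (length(zc) > 0) {
      Z <- X[, zc, drop = FALSE]
      V <- V + Z %*% G %*% t(Z)
    }
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    logdetV <- logdetV + 2 * sum(log(diag(ch))) * pat$n_g
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    Vi_Y <- backsolve(ch, forwardsolve(t(ch), pat$Y))
    A <- A + pat$n_g * crossprod(X, Vi_X)
    b <- b + crossprod(X, rowSums(Vi_Y))[, 1]
    qsum <- qsum + sum(pat$Y * Vi_Y)
  }
  chA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(chA)) return(-Inf)
  beta <- backsolve(chA, forwardsolve(t(chA), b))
  rss <- qsum - sum(beta * b)
  -0.5 * ((rd$N - p) * log(2 * pi) + logdetV + 2 * sum(log(diag(chA))) + rss)
}

# Maximize the profiled REML criterion over theta with jittered restarts.
# Returns theta, loglik and the GLS details at the optimum.
reml_fit <- function(rd, random = "both", n_restarts = 5L, tol = 1e-8) {
  nt <- n_theta(random)
  if (nt == 0) {
    det0 <- reml_profiled(rd, numeric(0), "none", details = TRUE)
    return(list(theta = numeric(0), loglik = det0$loglik, details = det0,
                converged = TRUE, random = "none"))
  }
  lower <- if (random == "both") c(0, -Inf, 0) else 0
  upper <- rep(1e6, nt)
  if (random == "both") upper[2] <- Inf
  # Exact interpolation (diverging criterion) is detected upstream in
  # fit_response_model(); any non-finite value here is treated as infeasible.
  objective <- function(th) {
    v <- reml_profiled(rd, th, random)
    if (!is.finite(v)) return(1e12)
    -v
  }
  starts <- list(rep(1, nt), rep(0.5, nt), rep(2, nt))
  if (random == "both") starts[[2]][2] <- 0.3
  best <- NULL
  conv <- FALSE
  for (r in seq_len(max(1L, n_restarts))) {
    st <- if (r <= length(starts)) {
      starts[[r]]
    } else {
      pmax(lower[seq_len(nt)] * 0, abs(rnorm(nt, 1, 0.7)))
    }
    fit <- tryCatch(
      nlminb(st, objective, lower = lower, upper = upper,
             control = list(rel.tol = tol, iter.max = 500L)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective - 1e-10) {
      best <- fit
      conv <- fit$convergence == 0
    } else if (abs(fit$objective - best$objective) <= 1e-6 &&
                 fit$convergence == 0) {
      conv <- TRUE
    }
    if (r >= 2 && conv) break
  }
  if (is.null(best)) {
    return(list(theta = rep(NA_real_, nt), loglik = NA_real_, details = NULL,
                converged = FALSE, random = random))
  }
  det0 <- reml_profiled(rd, best$par, random, details = TRUE)
  list(theta = best$par, loglik = -best$objective, details = det0,
       converged = conv && !is.null(det0), random = random)
}

# Variance components on the SD scale from a profiled fit.
extract_varcomp <- function(fit) {
  sig2 <- fit$details$sigma2
  lam <- lambda_matrix(fit$theta, fit$random)
  out <- list(sd_error = sqrt(sig2), sd_alpha = 0, sd_beta = 0,
              rho = NA_real_)
  if (fit$random == "none") return(out)
  G <- sig2 * (lam %*% t(lam))
  if (fit$random == "both") {
    out$sd_alpha <- sqrt(G[1, 1])
    out$sd_beta <- sqrt(G[2, 2])
    out$rho <- if (out$sd_alpha > 1e-8 && out$sd_beta > 1e-8) {
      G[1, 2] / (out$sd_alpha * out$sd_beta)
    } else {
      NA_real_
    }
  } else if (fit$random == "intercept") {
    out$sd_alpha <- sqrt(G[1, 1])
  } else {
    out$sd_beta <- sqrt(G[1, 1])
  }
  out
}

#' Tail probability and quantile of a 50:50 chi-square mixture
#'
#' Reference distribution for likelihood-ratio tests of a variance component
#' on the boundary of its parameter space: an equal mixture of two
#' chi-square distributions whose degrees of freedom depend on how many
#' parameters (variance, and covariance with a retained effect) are removed.
#' A chi-square with 0 degrees of freedom is a point mass at 0.
#'
#' @param q LRT statistic (nonnegative).
#' @param p Upper-tail probability.
#' @param dfs Two degrees of freedom, e.g. `c(1, 2)` when a correlated
#'   random effect is removed from a model that keeps another one, `c(0, 1)`
#'   when the sole random effect is removed.
#' @return `pchisq_mix`: the upper-tail probability P(Q >= q);
#'   `qchisq_mix`: the quantile with upper-tail probability `p`.
#' @examples
#' pchisq_mix(2.706, dfs = c(0, 1))  # ~0.05
#' qchisq_mix(0.05, dfs = c(1, 2))
#' @export
pchisq_mix <- function(q, dfs = c(1, 2)) {
  stopifnot(length(dfs) == 2)
  vapply(q, function(qq) {
    if (qq <= 0) return(1)
    mean(vapply(dfs, function(df) {
      if (df == 0) 0 else pchisq(qq, df, lower.tail = FALSE)
    }, numeric(1)))
  }, numeric(1))
}

#' @rdname pchisq_mix
#' @export
qchisq_mix <- function(p = 0.05, dfs = c(1, 2)) {
  stopifnot(length(p) == 1, p > 0, p < 1)
  if (pchisq_mix(0, dfs) <= p) return(0)
  uniroot(function(q) pchisq_mix(q, dfs) - p, c(1e-12, 200),
          tol = 1e-10)$root
}
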