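# Independent oracles, deliberately coded differently from the package:
# dense-matrix REML criterion with a direct (sd_alpha, sd_beta, rho,
# sd_error) parameterization, and a textbook Spearman formula for untied
# ranks.

# REML log-likelihood built subject by subject with dense solves.
oracle_reml_loglik <- function(d, sa, sb, rho, se) {
  subjects <- split(d, d$subject_id)
  D <- matrix(c(sa^2, rho * sa * sb, rho * sa * sb, sb^2), 2, 2)
  A <- matrix(0, 2, 2)
  b <- numeric(2)
  qsum <- 0
  logdet <- 0
  N <- 0
  for (s in subjects) {
    X <- cbind(1, s$load_code)
    V <- X %*% D %*% t(X) + se^2 * diag(nrow(X))
    Vi <- solve(V)
    logdet <- logdet + determinant(V, logarithm = TRUE)$modulus
    A <- A + t(X) %*% Vi %*% X
    b <- b + t(X) %*% Vi %*% s$delta
    qsum <- qsum + t(s$delta) %*% Vi %*% s$delta
    N <- N + nrow(X)
  }
  beta <- solve(A, b)
  as.numeric(-0.5 * ((N - 2) * log(2 * pi) + logdet +
                       determinant(A, logarithm = TRUE)$modulus +
                       (qsum - t(beta) %*% b)))
}

# Brute-force REML maximization over the four variance/correlation
# parameters from several starts.
oracle_reml_fit <- function(d) {
  obj <- function(par) {
    v <- tryCatch(
      oracle_reml_loglik(d, par[1], par[2], par[3], par[4]),
      error = function(e) -Inf
    )
    if (!is.finite(v)) return(1e10)
    -v
  }
  sd0 <- stats::sd(d$delta)
  best <- NULL
  for (st in list(c(sd0, sd0, 0, sd0) / 2,
                  c(sd0, sd0 / 4, 0.3, sd0 / 2),
                  c(sd0 / 4, sd0, -0.3, sd0 / 2))) {
    res <- stats::optim(st, obj, method = "L-BFGS-B",
                        lower = c(0, 0, -0.99, 1e-4),
                        upper = c(Inf, Inf, 0.99, Inf),
                        control = list(factr = 1e4, maxit = 500))
    if (is.null(best) || res$value < best$value) best <- res
  }
  # GLS fixed effects at the optimum
  subjects <- split(d, d$subject_id)
  par <- best$par
  D <- matrix(c(par[1]^2, par[3] * par[1] * par[2],
                par[3] * par[1] * par[2], par[2]^2), 2, 2)
  A <- matrix(0, 2, 2)
  b <- numeric(2)
  for (s in subjects) {
    X <- cbind(1, s$load_code)
    V <- X %*% D %*% t(X) + par[4]^2 * diag(nrow(X))
    Vi <- solve(V)
    A <- A + t(X) %*% Vi %*% X
    b <- b + t(X) %*% Vi %*% s$delta
  }
  beta <- solve(A, b)
  list(mu_alpha = beta[1], mu_beta = beta[2],
       sd_alpha = par[1], sd_beta = par[2], rho = par[3], sd_error = par[4],
       loglik = -best$value)
}

# Spearman correlation via 1 - 6*sum(d^2)/(n(n^2-1)); valid without ties.
oracle_spearman <- function(x, y) {
  stopifnot(!anyDuplicated(x), !anyDuplicated(y))
  dd <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(dd^2) / (n * (n^2 - 1))
}

# Noise-free change data delta = mu_a + mu_b * l for every subject.
noise_free_changes <- function(n_subjects, mu_a, mu_b) {
  tidyr::expand_grid(subject_id = seq_len(n_subjects),
                     load_code = c(-1, 0, 1)) |>
    dplyr::mutate(delta = mu_a + mu_b * load_code)
}
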