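test_that("noise-free common response is an exact boundary fit", {
  d <- noise_free_changes(5, mu_a = 5, mu_b = 2)
  fit <- fit_response_model(d)
  expect_true(fit$converged)
  expect_equal(fit$mu_alpha_hat, 5)
  expect_equal(fit$mu_beta_hat, 2)
  expect_equal(fit$sd_alpha_hat, 0)
  expect_equal(fit$sd_beta_hat, 0)
  expect_equal(fit$sd_error_hat, 0)
  expect_true(all(fit$boundary))
  expect_equal(fit$p_mu_alpha, 0)   # nonzero estimate, zero noise
  expect_equal(fit$p_sd_alpha, 1)   # no variance evidence at all
})

test_that("two flat subjects split into pure intercept heterogeneity", {
  d <- tibble::tibble(
    subject_id = rep(1:2, each = 3),
    load_code = rep(c(-1, 0, 1), 2),
    delta = c(0, 0, 0, 10, 10, 10)
  )
  fit <- fit_response_model(d)
  expect_equal(fit$mu_alpha_hat, 5)
  expect_equal(fit$mu_beta_hat, 0)
  expect_gt(fit$sd_alpha_hat, 0)
  expect_equal(fit$sd_beta_hat, 0)
  expect_equal(ci_sd(fit, "alpha")[1], fit$sd_alpha_hat)  # excludes 0
})

test_that("REML estimates agree with brute-force optimization and lme4", {
  skip_if_not_installed("lme4")
  cfg <- sim_config(n_subjects = 3, mu_alpha = 8, sd_alpha = 4,
                    mu_beta = 2, sd_beta = 2, sd_error = 3, seed = 17)
  d <- simulate_change_values(cfg)
  fit <- fit_response_model(d)
  oracle <- oracle_reml_fit(d)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
  expect_equal(fit$mu_alpha_hat, oracle$mu_alpha, tolerance = 1e-3)
  expect_equal(fit$mu_beta_hat, oracle$mu_beta, tolerance = 1e-3)
  expect_equal(fit$sd_alpha_hat, oracle$sd_alpha, tolerance = 1e-3)
  expect_equal(fit$sd_beta_hat, oracle$sd_beta, tolerance = 1e-3)
  expect_equal(fit$sd_error_hat, oracle$sd_error, tolerance = 1e-3)

  cfg24 <- sim_config(seed = 1)
  d24 <- simulate_change_values(cfg24)
  fit24 <- fit_response_model(d24)
  m <- lme4::lmer(delta ~ load_code + (load_code | subject_id), data = d24,
                  REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(fit24$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-6)
  expect_equal(fit24$mu_alpha_hat, unname(lme4::fixef(m)[1]), tolerance = 1e-5)
  expect_equal(fit24$mu_beta_hat, unname(lme4::fixef(m)[2]), tolerance = 1e-5)
  expect_equal(fit24$sd_alpha_hat, vc$sdcor[1], tolerance = 1e-4)
  expect_equal(fit24$sd_beta_hat, vc$sdcor[2], tolerance = 1e-4)
  expect_equal(fit24$sd_error_hat, vc$sdcor[4], tolerance = 1e-4)
  # reduced models used by the boundary LRT also match lme4
  rd <- mechmarker:::make_reml_data(d24$subject_id, d24$load_code, d24$delta)
  m_ri <- lme4::lmer(delta ~ load_code + (1 | subject_id), data = d24,
                     REML = TRUE)
  m_rs <- lme4::lmer(delta ~ load_code + (0 + load_code | subject_id),
                     data = d24, REML = TRUE)
  expect_equal(mechmarker:::reml_fit(rd, "intercept")$loglik,
               as.numeric(stats::logLik(m_ri)), tolerance = 1e-6)
  expect_equal(mechmarker:::reml_fit(rd, "slope")$loglik,
               as.numeric(stats::logLik(m_rs)), tolerance = 1e-6)
})

test_that("balanced-design identities hold for the fixed effects", {
  cfg <- sim_config(n_subjects = 16, seed = 23)
  d <- simulate_change_values(cfg)
  fit <- fit_response_model(d)
  # average slope equals half the spread of the load-level means, i.e. no
  # trend in level-specific means iff the average slope is 0
  level_means <- tapply(d$delta, d$load_code, mean)
  expect_equal(fit$mu_beta_hat,
               unname((level_means["1"] - level_means["-1"]) / 2),
               tolerance = 1e-6)
  # with centered load codes the mean intercept is the grand mean
  expect_equal(fit$mu_alpha_hat, mean(d$delta), tolerance = 1e-6)
})

test_that("mixture chi-square reference behaves as the boundary theory says", {
  expect_equal(pchisq_mix(0, c(1, 2)), 1)
  expect_equal(pchisq_mix(0, c(0, 1)), 1)
  expect_equal(pchisq_mix(2.706, c(0, 1)),
               0.5 * pchisq(2.706, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(pchisq_mix(2.706, c(0, 1)), 0.05, tolerance = 1e-3)
  q12 <- qchisq_mix(0.05, c(1, 2))
  expect_equal(pchisq_mix(q12, c(1, 2)), 0.05, tolerance = 1e-8)
  expect_gt(q12, qchisq(0.95, 1))
  expect_lt(q12, qchisq(0.95, 2))
})

test_that("Wald inference follows the normal reference", {
  cfg <- sim_config(n_subjects = 24, seed = 3)
  fit <- fit_response_model(simulate_change_values(cfg))
  tm <- test_mean(fit, "beta")
  z <- fit$mu_beta_hat / fit$se_mu_beta
  expect_equal(tm$p.value, 2 * pnorm(-abs(z)), tolerance = 1e-12)
  expect_equal(tm$conf.low, fit$mu_beta_hat - qnorm(0.975) * fit$se_mu_beta,
               tolerance = 1e-12)
  expect_equal(unname(unlist(tidy(fit)[tidy(fit)$term == "mu_beta",
                                       c("estimate", "p.value")])),
               c(tm$estimate, tm$p.value))
})

test_that("profile SD intervals cover the truth and match the LRT at 0", {
  # interval/test consistency: lower bound is 0 iff the boundary LRT keeps 0
  cfg <- sim_config(n_subjects = 24, sd_beta = 0, seed = 41)
  fit0 <- fit_response_model(simulate_change_values(cfg))
  ci0 <- ci_sd(fit0, "beta")
  expect_equal(ci0[1], 0)
  expect_true(fit0$p_sd_beta > 0.05)
  # coverage spot-check at strong heterogeneity
  cfg2 <- sim_config(n_subjects = 100, sd_alpha = 10, seed = 42)
  fit2 <- fit_response_model(simulate_change_values(cfg2))
  ci2 <- ci_sd(fit2, "alpha")
  expect_lt(ci2[1], 10)
  expect_gt(ci2[2], 10)
  expect_gt(ci2[1], 0)  # and the test agrees sd_alpha > 0
  expect_lt(fit2$p_sd_alpha, 0.05)
  # interval contains the point estimate
  expect_lte(ci2[1], fit2$sd_alpha_hat)
  expect_gte(ci2[2], fit2$sd_alpha_hat)
})

test_that("degenerate and malformed inputs are handled as contracts say", {
  # all-identical deltas: boundary fit, not an exception
  d <- tidyr::expand_grid(subject_id = 1:4, load_code = c(-1, 0, 1))
  d$delta <- 3
  fit <- fit_response_model(d)
  expect_equal(fit$mu_alpha_hat, 3)
  expect_equal(fit$sd_alpha_hat, 0)
  expect_true(all(fit$boundary))
  # too few subjects / load levels
  expect_error(fit_response_model(d[d$subject_id == 1, ]),
               class = "mechmarker_input_error")
  expect_error(fit_response_model(d[d$load_code == 0, ]),
               class = "mechmarker_input_error")
  # ambiguous multi-marker slice must be refused
  d$marker <- rep(c("COMP", "MMP-3"), length.out = nrow(d))
  expect_error(fit_response_model(d), class = "mechmarker_input_error")
})
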