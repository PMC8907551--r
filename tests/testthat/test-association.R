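change_slice <- function(deltas_by_load, subject_ids = NULL) {
  loads <- as.integer(names(deltas_by_load))
  purrr::imap_dfr(deltas_by_load, function(vals, ld) {
    tibble::tibble(
      subject_id = if (is.null(subject_ids)) seq_along(vals) else subject_ids,
      load_code = as.integer(ld),
      delta = vals
    )
  })
}

test_that("individual slopes equal the closed form on complete loads", {
  expect_equal(individual_slopes(tibble::tibble(
    subject_id = 1, load_code = c(-1, 0, 1), delta = c(0, 5, 10)))$slope, 5)
  expect_equal(individual_slopes(tibble::tibble(
    subject_id = 1, load_code = c(-1, 0, 1), delta = c(3, 3, 3)))$slope, 0)
  expect_equal(individual_slopes(tibble::tibble(
    subject_id = 1, load_code = c(-1, 0, 1), delta = c(2, 9, 4)))$slope, 1)
  # property: OLS slope == (delta(+1) - delta(-1)) / 2 for any values
  set.seed(1)
  d <- tidyr::expand_grid(subject_id = 1:20, load_code = c(-1L, 0L, 1L))
  d$delta <- rnorm(nrow(d), sd = 10)
  sl <- individual_slopes(d)
  wide <- tidyr::pivot_wider(d, names_from = "load_code",
                             values_from = "delta")
  expect_equal(sl$slope, (wide$`1` - wide$`-1`) / 2, tolerance = 1e-12)
  # subjects with < 2 load levels are skipped with a log message
  expect_message(
    out <- individual_slopes(d[!(d$subject_id == 1 & d$load_code != 0), ]),
    "skipped")
  expect_false(1 %in% out$subject_id)
})

test_that("load-averaged Spearman matches the textbook rank formula", {
  set.seed(7)
  a <- change_slice(list(`-1` = rnorm(6), `0` = rnorm(6), `1` = rnorm(6)))
  b <- change_slice(list(`-1` = rnorm(6), `0` = rnorm(6), `1` = rnorm(6)))
  per_load <- vapply(c(-1, 0, 1), function(l) {
    oracle_spearman(a$delta[a$load_code == l], b$delta[b$load_code == l])
  }, numeric(1))
  expect_equal(average_spearman(a, b), mean(per_load), tolerance = 1e-12)
  # perfect dependence limits
  expect_equal(average_spearman(a, a), 1)
  flipped <- dplyr::mutate(a, delta = -delta)
  expect_equal(average_spearman(a, flipped), -1)
  # invariance under strictly monotone transforms within load levels
  warped <- dplyr::mutate(b, delta = exp(delta / 2))
  expect_equal(average_spearman(a, warped), average_spearman(a, b))
  # sparse load levels are dropped; empty input errors
  a_small <- a[a$subject_id <= 2 | a$load_code == 0, ]
  expect_warning(r <- average_spearman(a_small, a_small), "dropped")
  expect_equal(r, 1)
  expect_error(
    suppressWarnings(average_spearman(a[a$subject_id <= 2, ],
                                      b[b$subject_id <= 2, ])),
    class = "mechmarker_correlation_error")
})

test_that("bootstrap Fisher-z inference is reproducible and sane in limits", {
  set.seed(11)
  a <- change_slice(list(`-1` = rnorm(12), `0` = rnorm(12), `1` = rnorm(12)))
  b <- change_slice(list(`-1` = rnorm(12), `0` = rnorm(12), `1` = rnorm(12)))
  est1 <- bootstrap_correlation_inference(a, b, n_boot = 300, seed = 5)
  est2 <- bootstrap_correlation_inference(a, b, n_boot = 300, seed = 5)
  expect_identical(est1, est2)
  expect_true(est1$conf.low >= -1 && est1$conf.high <= 1)
  expect_true(est1$conf.low <= est1$rho && est1$rho <= est1$conf.high)
  # perfect dependence: upper bound 1, p vanishes
  self <- bootstrap_correlation_inference(a, a, n_boot = 300, seed = 5)
  expect_equal(self$rho, 1)
  expect_equal(self$conf.high, 1)
  expect_lt(self$p.value, 1e-6)
  expect_error(bootstrap_correlation_inference(a, b, n_boot = 50, seed = 1),
               class = "mechmarker_input_error")
})

test_that("bootstrap test keeps roughly nominal size under independence", {
  n_sets <- 60
  rej <- logical(n_sets)
  for (i in seq_len(n_sets)) {
    set.seed(1000 + i)
    a <- change_slice(list(`-1` = rnorm(24), `0` = rnorm(24), `1` = rnorm(24)))
    b <- change_slice(list(`-1` = rnorm(24), `0` = rnorm(24), `1` = rnorm(24)))
    rej[i] <- bootstrap_correlation_inference(a, b, n_boot = 200,
                                              seed = i)$p.value < 0.05
  }
  # 60 independent null datasets: ~5% rejections, generous binomial band
  expect_lte(mean(rej), 0.17)
})

test_that("slope correlations reproduce hand-computed Spearman values", {
  s <- function(v) tibble::tibble(subject_id = seq_along(v), slope = v)
  expect_equal(slope_correlation(s(1:4), s(1:4))$rho, 1)
  expect_equal(slope_correlation(s(1:4), s(4:1))$rho, -1)
  # sum of squared rank differences is 4, so rho = 1 - 6*4/(5*24) = 0.8
  r <- slope_correlation(s(c(1, 2, 3, 4, 5)), s(c(1, 3, 2, 5, 4)))
  expect_equal(r$rho, 0.8, tolerance = 1e-12)
  expect_equal(r$rho, oracle_spearman(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4)))
  expect_error(slope_correlation(s(1:2), s(1:2)),
               class = "mechmarker_correlation_error")
})

test_that("correlation matrices are symmetric with unit diagonal and pick up
           shared latent slope structure", {
  # two markers driven by a shared latent slope, one independent
  set.seed(3)
  n <- 40
  latent <- rnorm(n, sd = 4)
  mk_changes <- function(marker, slope) {
    tidyr::expand_grid(subject_id = seq_len(n), load_code = c(-1L, 0L, 1L)) |>
      dplyr::mutate(marker = marker, timepoint = "t1", scale = "relative",
                    delta = slope[subject_id] * load_code +
                      rnorm(dplyr::n(), sd = 1))
  }
  changes <- dplyr::bind_rows(
    mk_changes("COMP", latent),
    mk_changes("MMP-3", latent),
    mk_changes("MMP-9", rnorm(n, sd = 4))
  )
  cm <- correlation_matrix(changes, kind = "slope")
  expect_equal(unname(diag(cm$rho)), rep(1, 3))
  expect_identical(cm$rho, t(cm$rho))
  linked <- cm$rho["COMP@t1", "MMP-3@t1"]
  unlinked <- abs(cm$rho["COMP@t1", "MMP-9@t1"])
  expect_gt(linked, 0.8)
  expect_lt(unlinked, 0.4)
  expect_lt(cm$p["COMP@t1", "MMP-3@t1"], 0.001)
})
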