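# Per-subject RNG streams: each subject (x marker) gets its own substream
# seeded from the config seed, so enlarging the study never perturbs the
# draws of earlier subjects.
subject_seed <- function(seed, i, salt = 0L) {
  x <- (as.numeric(seed) %% 2147483629) * 48271 +
    as.numeric(i) * 69621 + as.numeric(salt) * 40692
  as.integer(x %% 2147483629) + 1L
}

with_seed_local <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Draw (alpha, beta) for one subject from the bivariate normal response
# distribution; z must be two standard normal deviates.
draw_random_effects <- function(z, mu_alpha, sd_alpha, mu_beta, sd_beta, rho) {
  alpha <- mu_alpha + sd_alpha * z[1]
  beta <- mu_beta + sd_beta * (rho * z[1] + sqrt(1 - rho^2) * z[2])
  c(alpha = alpha, beta = beta)
}

#' Simulate change-from-baseline values under the individual response model
#'
#' Draws, for each subject, a random intercept/slope pair from the bivariate
#' normal response distribution of the configuration and emits the change
#' value `delta = alpha_i + beta_i * l + eps` for every load code `l`, with
#' i.i.d. normal residuals. This is the generating model of the mixed-effects
#' analysis (see [fit_response_model()]) and of the power study.
#'
#' @param config A [sim_config()] with a `seed`.
#' @param timepoint Post-test timepoint label the change values refer to
#'   (affects only the label and the RNG substream).
#' @return A tibble with one row per subject x load code: `subject_id`,
#'   `load_code`, `timepoint`, `delta` (change-scale points), and the
#'   generating subject effects `.alpha`, `.beta` (useful for calibration
#'   checks; drop them to mimic observed data).
#' @examples
#' cfg <- sim_config(n_subjects = 4, seed = 7)
#' simulate_change_values(cfg)
#' @export
simulate_change_values <- function(config, timepoint = "t1") {
  validate_sim_config(config)
  if (is.null(config$seed)) {
    abort("Invalid simulation config: `seed` must be set for simulation.",
          class = "mechmarker_config_error")
  }
  tp_salt <- match(timepoint, timepoint_levels())
  if (is.na(tp_salt)) tp_salt <- 97L
  loads <- config$load_codes
  rows <- purrr::map(seq_len(config$n_subjects), function(i) {
    with_seed_local(subject_seed(config$seed, i, tp_salt), {
      z <- rnorm(2)
      ab <- draw_random_effects(z, config$mu_alpha, config$sd_alpha,
                                config$mu_beta, config$sd_beta,
                                config$rho_alpha_beta)
      eps <- rnorm(length(loads), 0, config$sd_error)
      tibble(
        subject_id = 100L + i,
        load_code = loads,
        timepoint = timepoint,
        delta = ab[["alpha"]] + ab[["beta"]] * loads + eps,
        .alpha = ab[["alpha"]],
        .beta = ab[["beta"]]
      )
    })
  })
  dplyr::bind_rows(rows)
}

#' Simulate a raw-concentration marker panel
#'
#' Builds a long-format panel of raw serum concentrations emulating the
#' crossover loading experiment: per-subject lognormal baselines, the
#' subject's change-scale response injected multiplicatively at the post-test
#' timepoints (so the relative-change transform against the same-day t0 value
#' recovers the generating `delta` structure), duplicate measurements with
#' marker-specific intra-assay CV (lognormal multiplicative noise, keeping
#' concentrations positive), and detection-limit flagging.
#'
#' The change-scale response at post-test timepoint `t` for subject `i`,
#' load `l` is `profile_t * (alpha_i + beta_i * l + eps_ilt)` with the
#' marker's own response parameters; pre-test rows (`t-1`, `t0`) carry the
#' subject baseline. Day-to-day baseline drift is not modelled.
#'
#' @param config A [sim_config()] with a `seed`; `config$markers` must
#'   provide `baseline_median`, `baseline_cv` and `cv_intra` for every
#'   marker.
#' @return A marker-panel tibble with columns `subject_id`, `marker`,
#'   `load_pct`, `load_code`, `timepoint`, `replicate`, `concentration`,
#'   `out_of_range`.
#' @examples
#' cfg <- sim_config(n_subjects = 3, seed = 11)
#' panel <- simulate_concentration_panel(cfg)
#' head(panel)
#' @export
simulate_concentration_panel <- function(config) {
  validate_sim_config(config)
  if (is.null(config$seed)) {
    abort("Invalid simulation config: `seed` must be set for simulation.",
          class = "mechmarker_config_error")
  }
  mk <- config$markers
  needed <- c("marker", "baseline_median", "baseline_cv", "cv_intra",
              "lower_limit", "upper_limit",
              "mu_alpha", "sd_alpha", "mu_beta", "sd_beta", "sd_error")
  missing_cols <- setdiff(needed, names(mk))
  if (length(missing_cols) > 0) {
    abort(paste0("Invalid simulation config: `markers` lacks column(s) ",
                 paste0("`", missing_cols, "`", collapse = ", "), "."),
          class = "mechmarker_config_error")
  }
  if (anyNA(mk[needed])) {
    abort("Invalid simulation config: `markers` has missing per-marker values.",
          class = "mechmarker_config_error")
  }
  loads <- config$load_codes
  tps <- config$timepoints
  post <- intersect(tps, names(config$timepoint_profile))
  pre <- setdiff(tps, post)
  profile <- config$timepoint_profile

  rows <- purrr::map(seq_len(config$n_subjects), function(i) {
    purrr::map(seq_len(nrow(mk)), function(j) {
      m <- mk[j, ]
      with_seed_local(subject_seed(config$seed, i, 131L * j + 17L), {
        s_base <- sqrt(log(1 + (m$baseline_cv / 100)^2))
        baseline <- m$baseline_median * exp(s_base * rnorm(1))
        ab <- draw_random_effects(rnorm(2), m$mu_alpha, m$sd_alpha,
                                  m$mu_beta, m$sd_beta,
                                  config$rho_alpha_beta)
        grid <- tidyr::expand_grid(load_code = loads, timepoint = tps)
        eps <- rnorm(nrow(grid), 0, m$sd_error)
        delta <- ifelse(
          grid$timepoint %in% post,
          unname(profile[grid$timepoint]) *
            (ab[["alpha"]] + ab[["beta"]] * grid$load_code + eps),
          0
        )
        true_conc <- pmax(baseline * (1 + delta / 100), 0)
        s_dup <- sqrt(log(1 + (m$cv_intra / 100)^2))
        dup <- tidyr::expand_grid(row = seq_len(nrow(grid)), replicate = 1:2)
        noise <- if (s_dup > 0) {
          exp(s_dup * rnorm(nrow(dup)) - s_dup^2 / 2)
        } else {
          rep(1, nrow(dup))
        }
        conc <- true_conc[dup$row] * noise
        tibble(
          subject_id = 100L + i,
          marker = m$marker,
          load_pct = load_pct_from_code(grid$load_code[dup$row]),
          load_code = grid$load_code[dup$row],
          timepoint = grid$timepoint[dup$row],
          replicate = as.integer(dup$replicate),
          concentration = conc,
          out_of_range = conc < m$lower_limit | conc > m$upper_limit
        )
      })
    })
  })
  dplyr::bind_rows(rows) %>%
    arrange(.data$subject_id, .data$marker, .data$load_code,
            match(.data$timepoint, timepoint_levels()), .data$replicate)
}
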