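#' Simulation configuration for the loading-experiment generator
#'
#' Bundles the design of the crossover walking stress test (number of
#' subjects, load codes, timepoints) with the parameters of the individual
#' response model on the change scale: for subject `i` at load code `l`,
#'
#' \deqn{\delta_{il} = \alpha_i + \beta_i l + \epsilon_{il},}
#'
#' where `(alpha_i, beta_i)` are bivariate normal with means
#' (`mu_alpha`, `mu_beta`), standard deviations (`sd_alpha`, `sd_beta`) and
#' correlation `rho_alpha_beta`, and the residuals are i.i.d. normal with
#' standard deviation `sd_error`. The intercept `alpha_i` is the response at
#' 100% body weight; the slope `beta_i` is the change in response per load
#' level. All change-scale parameters are in percentage points.
#'
#' @param n_subjects Number of subjects (>= 2). Default 24, the sample size
#'   of the reference study design.
#' @param load_codes Strictly increasing integer load codes centered on 0.
#'   Default `c(-1, 0, 1)` for 80/100/120% body weight.
#' @param timepoints Ordered timepoint labels; must contain "t0" and at least
#'   one post-test timepoint.
#' @param mu_alpha,sd_alpha Mean and between-subject SD of the response at
#'   load code 0 (change-scale points).
#' @param mu_beta,sd_beta Mean and between-subject SD of the per-load-level
#'   slope (change-scale points per load level).
#' @param rho_alpha_beta Correlation of the random intercept and slope,
#'   in \[-1, 1\]. Default 0.
#' @param sd_error Residual SD of the change values. Default 5.
#' @param timepoint_profile Named numeric multipliers applied to the subject
#'   response at each post-test timepoint when building a raw concentration
#'   panel (the change-model parameters describe the peak response; later
#'   timepoints decay).
#' @param markers Per-marker specification tibble as returned by
#'   [default_marker_spec()]; used only by [simulate_concentration_panel()].
#' @param seed Integer RNG seed (required for reproducibility).
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_change_values()], [simulate_concentration_panel()],
#'   [read_sim_config()]
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg
#' @export
sim_config <- function(n_subjects = 24,
                       load_codes = c(-1L, 0L, 1L),
                       timepoints = timepoint_levels(),
                       mu_alpha = 5, sd_alpha = 5,
                       mu_beta = 5, sd_beta = 5,
                       rho_alpha_beta = 0,
                       sd_error = 5,
                       timepoint_profile = c(t1 = 1, t2 = 0.5, t3 = 0.2),
                       markers = default_marker_spec(),
                       seed = NULL) {
  cfg <- structure(
    list(
      n_subjects = as.integer(n_subjects),
      load_codes = as.integer(load_codes),
      timepoints = as.character(timepoints),
      mu_alpha = as.numeric(mu_alpha), sd_alpha = as.numeric(sd_alpha),
      mu_beta = as.numeric(mu_beta), sd_beta = as.numeric(sd_beta),
      rho_alpha_beta = as.numeric(rho_alpha_beta),
      sd_error = as.numeric(sd_error),
      timepoint_profile = timepoint_profile,
      markers = markers,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(field, msg) {
    abort(paste0("Invalid simulation config: `", field, "` ", msg, "."),
          class = "mechmarker_config_error")
  }
  if (length(cfg$n_subjects) != 1 || is.na(cfg$n_subjects) || cfg$n_subjects < 2) {
    bad("n_subjects", "must be a single integer >= 2")
  }
  lc <- cfg$load_codes
  if (length(lc) < 2 || any(diff(lc) <= 0)) {
    bad("load_codes", "must be strictly increasing")
  }
  if (abs(mean(lc)) > 1e-8) bad("load_codes", "must be centered on 0")
  for (f in c("sd_alpha", "sd_beta", "sd_error")) {
    v <- cfg[[f]]
    if (length(v) != 1 || is.na(v) || v < 0) bad(f, "must be a single value >= 0")
  }
  for (f in c("mu_alpha", "mu_beta")) {
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]])) bad(f, "must be a single number")
  }
  r <- cfg$rho_alpha_beta
  if (length(r) != 1 || is.na(r) || abs(r) > 1) {
    bad("rho_alpha_beta", "must lie in [-1, 1]")
  }
  if (!"t0" %in% cfg$timepoints) bad("timepoints", "must contain \"t0\"")
  post <- intersect(cfg$timepoints, post_timepoints())
  if (length(post) == 0) bad("timepoints", "must contain a post-test timepoint")
  if (!all(post %in% names(cfg$timepoint_profile))) {
    bad("timepoint_profile", "must name every post-test timepoint")
  }
  if (!is.null(cfg$seed) && (length(cfg$seed) != 1 || is.na(cfg$seed))) {
    bad("seed", "must be a single integer")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  subjects: %d, load codes: %s\n", x$n_subjects,
              paste(x$load_codes, collapse = ", ")))
  cat(sprintf("  response model: mu_alpha=%.3g sd_alpha=%.3g mu_beta=%.3g sd_beta=%.3g rho=%.3g sd_error=%.3g\n",
              x$mu_alpha, x$sd_alpha, x$mu_beta, x$sd_beta,
              x$rho_alpha_beta, x$sd_error))
  cat(sprintf("  timepoints: %s\n", paste(x$timepoints, collapse = ", ")))
  cat(sprintf("  markers: %d defined, seed: %s\n",
              nrow(x$markers), if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

#' Default per-marker panel specification
#'
#' Baseline distributions, assay precision, detection limits and response
#' parameters for the eight directly assayed serum markers (the CPII/C2C
#' ratio is derived downstream, not simulated). Baseline medians and spreads
#' are order-of-magnitude values typical of serum ELISA panels in healthy
#' adults; the change-scale response parameters mirror the qualitative
#' pattern of the reference study (strong transient COMP and MMP-3 responses
#' with positive load slopes, a delayed IL-6 rise, inter-individual MMP-9
#' variation without an average response, and essentially flat C2C and CPII).
#'
#' @return A tibble with one row per marker and columns `marker`,
#'   `baseline_median`, `baseline_cv` (between-subject geometric CV, %),
#'   `cv_intra` (duplicate intra-assay CV, %), `lower_limit`, `upper_limit`
#'   (detection limits on the concentration scale), and the change-scale
#'   response parameters `mu_alpha`, `sd_alpha`, `mu_beta`, `sd_beta`,
#'   `sd_error`.
#' @examples
#' default_marker_spec()
#' @export
default_marker_spec <- function() {
  tibble::tribble(
    ~marker,     ~baseline_median, ~baseline_cv, ~cv_intra, ~lower_limit, ~upper_limit, ~mu_alpha, ~sd_alpha, ~mu_beta, ~sd_beta, ~sd_error,
    "COMP",       800,   25, 3.5, 0,   Inf, 29,  12,  5,   4,   6,
    "MMP-3",       20,   40, 3.0, 0,   Inf, 27,  10,  8,   4,   6,
    "MMP-9",      400,   50, 4.0, 0,   Inf,  0,   9, -2,   6,  10,
    "ADAMTS-4",   200,   80, 6.0, 20, 2000,  3,   0,  1,   8,   8,
    "PRG-4",      100,   35, 5.0, 0,   Inf,  0,   0,  0,   0,  15,
    "IL-6",       1.5,   60, 4.5, 0,   Inf,  6,   5, -2,   5,   8,
    "C2C",        200,   20, 4.0, 0,   Inf,  0,   0,  0,   0,   9,
    "CPII",      1000,   30, 3.0, 0,   Inf,  5,   0,  2,  14,  11
  )
}

#' Read a simulation configuration from a YAML file
#'
#' The file may set any argument of [sim_config()]; a nested `markers`
#' section (one sub-section per marker name) overrides columns of
#' [default_marker_spec()] for the named markers.
#'
#' @param path Path to a YAML configuration file.
#' @return A `sim_config` object.
#' @examples
#' f <- tempfile(fileext = ".yml")
#' writeLines(c("n_subjects: 12", "sd_error: 7", "seed: 42",
#'              "markers:", "  COMP:", "    cv_intra: 5"), f)
#' read_sim_config(f)
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  markers <- default_marker_spec()
  if (!is.null(raw$markers)) {
    for (mk in names(raw$markers)) {
      if (!mk %in% markers$marker) {
        warn(paste0("Unknown marker in config: ", mk, " (row added)."))
        markers <- dplyr::bind_rows(markers, tibble(marker = mk))
      }
      for (col in names(raw$markers[[mk]])) {
        if (!col %in% names(markers)) {
          abort(paste0("Invalid simulation config: unknown marker field `",
                       col, "`."), class = "mechmarker_config_error")
        }
        markers[markers$marker == mk, col] <- raw$markers[[mk]][[col]]
      }
    }
    raw$markers <- NULL
  }
  if (!is.null(raw$timepoint_profile)) {
    raw$timepoint_profile <- unlist(raw$timepoint_profile)
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("Invalid simulation config: unknown field(s) ",
                 paste0("`", unknown, "`", collapse = ", "), "."),
          class = "mechmarker_config_error")
  }
  do.call(sim_config, c(raw, list(markers = markers)))
}
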