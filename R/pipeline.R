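#' Read a long-format marker panel from CSV
#'
#' Expects the documented long format: columns `subject_id`, `marker`,
#' `load_pct` (80/100/120) and/or `load_code` (-1/0/+1), `timepoint`
#' (t-1 ... t3), optional `replicate`, `concentration`, optional
#' `out_of_range`. Unknown extra columns are preserved; unknown marker
#' labels trigger a warning. Panel invariants (valid load mapping, no
#' duplicated keys, nonnegative unflagged concentrations) are enforced at
#' load time.
#'
#' @param path CSV file path.
#' @return A validated marker-panel tibble.
#' @export
read_panel <- function(path) {
  panel <- readr::read_csv(path, show_col_types = FALSE)
  if (!"load_code" %in% names(panel) && "load_pct" %in% names(panel)) {
    panel$load_code <- load_code_from_pct(panel$load_pct)
  }
  if (!"load_pct" %in% names(panel) && "load_code" %in% names(panel)) {
    panel$load_pct <- load_pct_from_code(panel$load_code)
  }
  check_panel(panel)
  bad <- which(!complete.cases(panel[c("subject_id", "marker", "load_code",
                                       "timepoint", "concentration")]))
  if (length(bad) > 0) {
    abort(paste0("Malformed panel rows (missing key or value) at line(s): ",
                 paste(head(bad + 1L, 20), collapse = ", "), "."),
          class = "mechmarker_input_error")
  }
  if (all(c("load_pct", "load_code") %in% names(panel))) {
    mismatch <- panel$load_code != load_code_from_pct(panel$load_pct)
    if (any(mismatch)) {
      abort(paste0("Inconsistent load_pct/load_code at line(s): ",
                   paste(head(which(mismatch) + 1L, 20), collapse = ", "), "."),
            class = "mechmarker_integrity_error")
    }
  }
  key <- paste(panel_key(panel),
               if ("replicate" %in% names(panel)) panel$replicate else 1L)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(paste0("Duplicated (subject, marker, load, timepoint, replicate) ",
                 "key: ", gsub("\r", ", ", dup), "."),
          class = "mechmarker_integrity_error")
  }
  unflagged <- if ("out_of_range" %in% names(panel)) !panel$out_of_range else TRUE
  if (any(panel$concentration < 0 & unflagged)) {
    abort("Negative unflagged concentrations in panel.",
          class = "mechmarker_integrity_error")
  }
  unknown <- setdiff(unique(panel$marker), marker_levels())
  if (length(unknown) > 0) {
    warn(paste0("Unknown marker label(s): ", paste(unknown, collapse = ", "), "."))
  }
  if (!all(panel$timepoint %in% timepoint_levels())) {
    abort("Timepoint labels must be t-1, t0, t1, t2, t3.",
          class = "mechmarker_input_error")
  }
  panel
}

#' Run the full two-stage suitability analysis
#'
#' Orchestrates the whole pipeline on a raw marker panel (read with
#' [read_panel()] or simulated with [simulate_concentration_panel()]):
#' duplicate averaging and intra-assay CV summary, ratio-marker
#' construction, exclusions, change tables on both scales, one
#' random-intercept/random-slope REML fit per marker x timepoint x scale
#' (yielding both the response and the slope summaries), the two-stage
#' criteria gate on the gating scale, and the correlation matrices of
#' changes and slopes over the selected combinations.
#'
#' @param panel Raw marker-panel tibble, or `NULL` to simulate.
#' @param config [sim_config()] used when `panel` is `NULL` (exactly one
#'   input source must be given).
#' @param gating_scale Scale the criteria gate runs on (default
#'   `"relative"`; the other scale is reported as a sensitivity analysis).
#' @param alpha Significance level of the gate.
#' @param overrides Criterion-I override tibble (`marker`, `timepoint`,
#'   `reason`); see [flag_override_candidates()].
#' @param exclusion_rules Explicit (subject, marker) exclusions.
#' @param cap,cap_timepoints Relative-change cap rule (see
#'   [select_shift_constant()]).
#' @param log_markers Markers log10(1+x)-transformed before absolute
#'   changes.
#' @param n_boot Bootstrap replicates for change-correlation p-values
#'   (0 skips them).
#' @param sd_ci Compute profile CIs for the SD estimates (slower).
#' @param seed Seed for the bootstrap (and the simulation when `panel` is
#'   `NULL` and `config$seed` is unset).
#' @param output_dir If non-`NULL`, results are also written as CSV via
#'   [write_tables()].
#' @return A `mechmarker_result` list: `panel` (preprocessed), `cv`,
#'   `exclusions`, `changes` (both scales), `fits` (response table),
#'   `gate`, `verdicts`, `correlations` (change- and slope-kind),
#'   `override_candidates`, `constants`, `manifest`.
#' @export
run_pipeline <- function(panel = NULL, config = NULL,
                         gating_scale = c("relative", "absolute"),
                         alpha = 0.05, overrides = NULL,
                         exclusion_rules = NULL, cap = 75,
                         cap_timepoints = c("t1", "t2"),
                         log_markers = "ADAMTS-4",
                         n_boot = 0L, sd_ci = FALSE, seed = 1L,
                         output_dir = NULL) {
  gating_scale <- match.arg(gating_scale)
  if (is.null(panel) == is.null(config)) {
    abort("Provide exactly one input source: `panel` or `config`.",
          class = "mechmarker_config_error")
  }
  if (!(alpha > 0 && alpha < 1)) {
    abort("`alpha` must lie in (0, 1).", class = "mechmarker_config_error")
  }
  if (is.null(panel)) {
    if (is.null(config$seed)) config$seed <- as.integer(seed)
    panel <- simulate_concentration_panel(config)
  }
  cv <- if ("replicate" %in% names(panel)) intra_assay_cv(panel) else NULL
  panel <- average_duplicates(panel)
  panel <- add_ratio_marker(panel)
  excl <- exclude_subjects(panel, rules = exclusion_rules,
                           detection_limit_rule = TRUE)
  panel <- excl$panel

  changes <- dplyr::bind_rows(
    build_change_table(panel, "relative", cap = cap,
                       cap_timepoints = cap_timepoints),
    build_change_table(panel, "absolute", log_markers = log_markers)
  )
  constants <- changes %>%
    distinct(.data$marker, .data$scale,
             shift_c = .data$shift_c %||% NA_real_,
             baseline_median_m = .data$baseline_median_m %||% NA_real_)

  fits <- fit_response_models(changes, sd_ci = sd_ci)

  gate_in <- fits %>% filter(.data$scale == gating_scale) %>% select(-"fit")
  candidates <- flag_override_candidates(gate_in, alpha)
  gate <- apply_criterion_one(gate_in, alpha = alpha, overrides = overrides)
  crit2 <- apply_criterion_two(gate_in, gate, alpha = alpha)

  selected <- crit2$decisions %>%
    filter(.data$selected) %>%
    select("marker", "timepoint")
  correlations <- if (nrow(selected) >= 2) {
    gating_changes <- changes %>% filter(.data$scale == gating_scale)
    list(
      change = correlation_matrix(gating_changes, combos = selected,
                                  kind = "change", n_boot = n_boot,
                                  seed = seed),
      slope = correlation_matrix(gating_changes, combos = selected,
                                 kind = "slope")
    )
  } else {
    inform("Fewer than 2 selected combinations: no correlation matrices.")
    NULL
  }

  result <- structure(list(
    panel = panel, cv = cv, exclusions = excl$report, changes = changes,
    fits = fits %>% select(-"fit"), gate = crit2$decisions,
    verdicts = crit2$verdicts, correlations = correlations,
    override_candidates = candidates, constants = constants,
    manifest = list(
      package_version = as.character(utils::packageVersion("mechmarker")),
      r_version = R.version.string,
      gating_scale = gating_scale, alpha = alpha, cap = cap,
      n_boot = n_boot, seed = seed,
      input = if (is.null(config)) "panel" else "simulated",
      timestamp = NA_character_  # kept NA so reruns are byte-identical
    )
  ), class = "mechmarker_result")
  if (!is.null(output_dir)) write_tables(result, output_dir)
  result
}

#' @export
print.mechmarker_result <- function(x, ...) {
  cat("<mechmarker_result>\n")
  cat(sprintf("  %d markers, %d subjects, gating scale: %s\n",
              dplyr::n_distinct(x$fits$marker),
              dplyr::n_distinct(x$panel$subject_id),
              x$manifest$gating_scale))
  n_sel <- sum(x$gate$selected)
  cat(sprintf("  criterion I: %d combination(s) selected\n", n_sel))
  if (nrow(x$verdicts) > 0) {
    suitable <- x$verdicts$marker[x$verdicts$suitable]
    cat(sprintf("  criterion II suitable: %s\n",
                if (length(suitable)) paste(suitable, collapse = ", ")
                else "none"))
  } else {
    cat("  criterion II suitable: none\n")
  }
  invisible(x)
}

round_cols <- function(tab, cols, digits) {
  for (cl in intersect(cols, names(tab))) {
    tab[[cl]] <- round(tab[[cl]], digits)
  }
  tab
}

#' Write pipeline results as CSV tables
#'
#' Writes the response/slope summary tables (estimates to 1 decimal,
#' p-values to 3 decimals, matching the published table layout), the gate
#' decisions and marker verdicts, the correlation matrices, the per-marker
#' change constants and the run manifest into a directory. Every exported
#' number is taken from the fitted objects; nothing is recomputed at the
#' report layer.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(result, dir) {
  stopifnot(inherits(result, "mechmarker_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(tab, name) {
    p <- file.path(dir, name)
    readr::write_csv(tab, p)
    paths <<- c(paths, p)
  }
  est_cols <- function(stub) {
    c(stub, paste0(stub, "_low"), paste0(stub, "_high"))
  }
  for (sc in unique(result$fits$scale)) {
    tab <- result$fits %>% filter(.data$scale == sc)
    response <- tab %>%
      select("marker", "timepoint", all_of(est_cols("mu_alpha")),
             "p_mu_alpha", all_of(est_cols("sd_alpha")), "p_sd_alpha") %>%
      round_cols(c(est_cols("mu_alpha"), est_cols("sd_alpha")), 1) %>%
      round_cols(c("p_mu_alpha", "p_sd_alpha"), 3)
    slope <- tab %>%
      select("marker", "timepoint", all_of(est_cols("mu_beta")),
             "p_mu_beta", all_of(est_cols("sd_beta")), "p_sd_beta") %>%
      round_cols(c(est_cols("mu_beta"), est_cols("sd_beta")), 1) %>%
      round_cols(c("p_mu_beta", "p_sd_beta"), 3)
    emit(response, paste0("response_", sc, ".csv"))
    emit(slope, paste0("slope_", sc, ".csv"))
  }
  emit(result$gate, "gate_decisions.csv")
  emit(result$verdicts, "marker_verdicts.csv")
  if (!is.null(result$cv)) emit(result$cv, "intra_assay_cv.csv")
  if (nrow(result$exclusions) > 0) emit(result$exclusions, "exclusions.csv")
  emit(result$constants, "change_constants.csv")
  if (!is.null(result$correlations)) {
    for (kind in names(result$correlations)) {
      cm <- result$correlations[[kind]]
      emit(as_tibble(cm$rho, rownames = "combo"),
           paste0("correlation_", kind, "_rho.csv"))
      if (!all(is.na(cm$p))) {
        emit(as_tibble(cm$p, rownames = "combo"),
             paste0("correlation_", kind, "_p.csv"))
      }
    }
  }
  writeLines(format_gate_report(result$gate, result$verdicts),
             file.path(dir, "gating_report.txt"))
  yaml::write_yaml(result$manifest, file.path(dir, "manifest.yml"))
  invisible(c(paths, file.path(dir, c("gating_report.txt", "manifest.yml"))))
}
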