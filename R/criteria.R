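#' Reference study summary tables
#'
#' Published response and dose-response summaries from a 24-subject
#' crossover walking stress-test study of the nine-marker serum panel, on
#' the relative-change scale: per marker x post-test timepoint, the
#' estimated mean and SD of the individual responses (`kind = "response"`)
#' or of the individual per-load-level slopes (`kind = "slope"`, available
#' only for the criterion-I-selected combinations), each with 95% CI and
#' p-value. These tables drive the worked gating example; p-values reported
#' as below .001 are stored as 0.0005.
#'
#' @param kind `"response"` (criterion I input) or `"slope"` (criterion II
#'   input).
#' @return A tibble with columns `marker`, `timepoint`, the printed
#'   estimates/CIs, and gating columns `mu_*`, `sd_*`, `p_mu_*`, `p_sd_*`
#'   named for the model quantity they summarize.
#' @examples
#' reference_fit_table("response")
#' @export
reference_fit_table <- function(kind = c("response", "slope")) {
  kind <- match.arg(kind)
  path <- system.file("extdata",
                      paste0("reference_", kind, "_relative.csv"),
                      package = "mechmarker", mustWork = TRUE)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  which <- if (kind == "response") "alpha" else "beta"
  tab[[paste0("mu_", which)]] <- tab$mean_estimate
  tab[[paste0("sd_", which)]] <- tab$sd_estimate
  tab[[paste0("p_mu_", which)]] <- tab$mean_p
  tab[[paste0("p_sd_", which)]] <- tab$sd_p
  tab$scale <- "relative"
  tab
}

#' Criterion I: does the marker respond to the stress test?
#'
#' For every marker x post-test timepoint, criterion Ia asks whether there
#' is on average a response to the walking exercise (mean-response p-value
#' below `alpha`) and criterion Ib whether there is inter-individual
#' variation in the response (response-SD p-value below `alpha`). A
#' combination passes criterion I when Ia or Ib holds; explicit override
#' rules can remove a passing combination with a recorded reason (e.g. a
#' significant but implausible negative mean inconsistent with the marker's
#' other timepoints). Overrides can only remove, never add.
#'
#' @param fits A tibble with columns `marker`, `timepoint`, `p_mu_alpha`,
#'   `p_sd_alpha` — a [fit_response_models()] result or
#'   [reference_fit_table()] — covering every marker x timepoint
#'   combination.
#' @param alpha Significance level (default 0.05; the framework applies no
#'   multiple-testing adjustment, each test is at the per-test level).
#' @param overrides Optional tibble with columns `marker`, `timepoint`,
#'   `reason`.
#' @param timepoints Post-test timepoints that must be covered.
#' @return A `gate_decision` tibble: per combination `crit_Ia`, `crit_Ib`,
#'   `crit_I`, `overridden`, `override_reason`, `selected`
#'   (= `crit_I` after overrides) and `alpha_level`.
#' @examples
#' gates <- apply_criterion_one(reference_fit_table("response"))
#' dplyr::filter(gates, selected)
#' @export
apply_criterion_one <- function(fits, alpha = 0.05, overrides = NULL,
                                timepoints = post_timepoints()) {
  need <- c("marker", "timepoint", "p_mu_alpha", "p_sd_alpha")
  missing_cols <- setdiff(need, names(fits))
  if (length(missing_cols) > 0) {
    abort(paste0("Criterion I input lacks column(s) ",
                 paste0("`", missing_cols, "`", collapse = ", "), "."),
          class = "mechmarker_input_error")
  }
  expected <- tidyr::expand_grid(marker = unique(fits$marker),
                                 timepoint = timepoints)
  gaps <- dplyr::anti_join(expected, fits, by = c("marker", "timepoint"))
  if (nrow(gaps) > 0) {
    abort(paste0("Gating incomplete; missing fits for: ",
                 paste(gaps$marker, gaps$timepoint, sep = "@",
                       collapse = ", "), "."),
          class = "mechmarker_gating_error")
  }
  out <- fits %>%
    filter(.data$timepoint %in% timepoints) %>%
    mutate(
      crit_Ia = .data$p_mu_alpha < alpha,
      crit_Ib = .data$p_sd_alpha < alpha,
      crit_I = .data$crit_Ia | .data$crit_Ib,
      overridden = FALSE,
      override_reason = NA_character_,
      alpha_level = alpha
    )
  if (!is.null(overrides) && nrow(overrides) > 0) {
    for (r in seq_len(nrow(overrides))) {
      hit <- out$marker == overrides$marker[r] &
        out$timepoint == overrides$timepoint[r]
      if (!any(hit)) next
      if (any(out$crit_I[hit])) {
        out$overridden[hit] <- TRUE
        out$override_reason[hit] <- overrides$reason[r] %||% "unspecified"
      }
    }
  }
  out <- out %>% mutate(selected = .data$crit_I & !.data$overridden)
  class(out) <- c("gate_decision", class(out))
  out
}

#' Criterion II: does the response depend on the magnitude of load?
#'
#' For every combination selected by criterion I, criterion IIa asks whether
#' the average individual slope of the change-load relationship differs
#' from 0, and IIb whether there is inter-individual variation in this
#' slope. A marker is *suitable* for assessing the dose-response
#' relationship when at least one of its selected combinations satisfies
#' IIa or IIb.
#'
#' @param slope_fits A tibble with columns `marker`, `timepoint`,
#'   `p_mu_beta`, `p_sd_beta` covering every selected combination — a
#'   [fit_response_models()] result on the slope model or
#'   [reference_fit_table]`("slope")`.
#' @param decisions A [apply_criterion_one()] result.
#' @param alpha Significance level.
#' @return A list with `decisions` (the gate table with `crit_IIa`,
#'   `crit_IIb`, `crit_II` filled in for selected combinations, `NA`
#'   elsewhere) and `verdicts` (per marker: `suitable` plus the supporting
#'   combination count).
#' @examples
#' gates <- apply_criterion_one(reference_fit_table("response"))
#' res <- apply_criterion_two(reference_fit_table("slope"), gates)
#' res$verdicts
#' @export
apply_criterion_two <- function(slope_fits, decisions, alpha = 0.05) {
  need <- c("marker", "timepoint", "p_mu_beta", "p_sd_beta")
  missing_cols <- setdiff(need, names(slope_fits))
  if (length(missing_cols) > 0) {
    abort(paste0("Criterion II input lacks column(s) ",
                 paste0("`", missing_cols, "`", collapse = ", "), "."),
          class = "mechmarker_input_error")
  }
  sel <- decisions %>% filter(.data$selected)
  gaps <- dplyr::anti_join(sel, slope_fits, by = c("marker", "timepoint"))
  if (nrow(gaps) > 0) {
    abort(paste0("Gating incomplete; missing slope fits for: ",
                 paste(gaps$marker, gaps$timepoint, sep = "@",
                       collapse = ", "), "."),
          class = "mechmarker_gating_error")
  }
  dec <- decisions %>%
    select(-dplyr::any_of(c("p_mu_beta", "p_sd_beta"))) %>%
    left_join(slope_fits %>%
                select("marker", "timepoint", "p_mu_beta", "p_sd_beta"),
              by = c("marker", "timepoint")) %>%
    mutate(
      crit_IIa = dplyr::if_else(.data$selected, .data$p_mu_beta < alpha, NA),
      crit_IIb = dplyr::if_else(.data$selected, .data$p_sd_beta < alpha, NA),
      crit_II = .data$crit_IIa | .data$crit_IIb
    )
  verdicts <- dec %>%
    filter(.data$selected) %>%
    group_by(.data$marker) %>%
    summarise(
      n_selected = dplyr::n(),
      n_crit_II = sum(.data$crit_II, na.rm = TRUE),
      suitable = any(.data$crit_II, na.rm = TRUE),
      .groups = "drop"
    )
  list(decisions = dec, verdicts = verdicts)
}

#' Flag candidate spurious criterion-I findings for review
#'
#' Helper for constructing the override list of [apply_criterion_one()]:
#' flags combinations that pass via a significant mean response whose sign
#' is negative while the marker's mean estimates at its other timepoints
#' average positive — the pattern of an isolated, implausible finding. The
#' flags are suggestions for human review, never applied automatically.
#'
#' @param fits A tibble with `marker`, `timepoint`, `mu_alpha`,
#'   `p_mu_alpha`.
#' @param alpha Significance level.
#' @return Tibble of flagged combinations with a prefilled `reason`.
#' @examples
#' flag_override_candidates(reference_fit_table("response"))
#' @export
flag_override_candidates <- function(fits, alpha = 0.05) {
  stopifnot(all(c("marker", "timepoint", "mu_alpha", "p_mu_alpha") %in%
                  names(fits)))
  fits %>%
    group_by(.data$marker) %>%
    mutate(other_mean = (sum(.data$mu_alpha) - .data$mu_alpha) /
             pmax(dplyr::n() - 1, 1)) %>%
    ungroup() %>%
    filter(.data$p_mu_alpha < alpha, .data$mu_alpha < 0,
           .data$other_mean > 0) %>%
    mutate(reason = paste0(
      "significant negative mean response inconsistent in sign with the ",
      "marker's other timepoints")) %>%
    select("marker", "timepoint", "reason")
}

#' Human-readable gating report
#'
#' @param decisions Gate table from [apply_criterion_one()] (optionally
#'   after [apply_criterion_two()]).
#' @param verdicts Optional marker verdicts from [apply_criterion_two()].
#' @return A character vector of report lines (invisibly printed with
#'   `cat()` when `print = TRUE`).
#' @param print Print the report to the console.
#' @export
format_gate_report <- function(decisions, verdicts = NULL, print = FALSE) {
  lines <- c("Criterion I: response to the stress test",
             "----------------------------------------")
  sel <- decisions %>% filter(.data$selected)
  for (mk in unique(decisions$marker)) {
    tps <- sel$timepoint[sel$marker == mk]
    lines <- c(lines, sprintf("  %-10s %s", mk,
                              if (length(tps)) paste(tps, collapse = ", ")
                              else "-"))
  }
  ov <- decisions %>% filter(.data$overridden)
  if (nrow(ov) > 0) {
    lines <- c(lines, "", "Overrides applied:")
    lines <- c(lines, sprintf("  %s @ %s: %s", ov$marker, ov$timepoint,
                              ov$override_reason))
  }
  if (!is.null(verdicts)) {
    lines <- c(lines, "", "Criterion II: dose-response suitability",
               "---------------------------------------")
    lines <- c(lines, sprintf("  %-10s %s", verdicts$marker,
                              ifelse(verdicts$suitable, "suitable",
                                     "not suitable")))
  }
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
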