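#' Normalized absolute change
#'
#' Change from the same-day baseline in units of the marker's pooled baseline
#' median: `(y_t - y_0) / m * 100`. A five-point change is a change of 5% of
#' the marker's typical baseline level, which makes absolute changes
#' comparable across markers with different units.
#'
#' @param y_t Concentration at a post-test timepoint.
#' @param y_0 Concentration at t0 (same subject, same test day).
#' @param m Pooled baseline median for the marker (see [baseline_median()]);
#'   must be positive.
#' @return The change in percentage points of the baseline median.
#' @examples
#' absolute_change(105, 100, 100)  # 5
#' @export
absolute_change <- function(y_t, y_0, m) {
  if (any(m <= 0, na.rm = TRUE)) {
    abort("Baseline median `m` must be positive.",
          class = "mechmarker_domain_error")
  }
  (y_t - y_0) / m * 100
}

#' Shifted relative change
#'
#' Percent change from the same-day baseline with the denominator shifted by
#' a constant `c >= 0`: `(y_t - y_0) / (y_0 + c) * 100`. The shift stabilizes
#' relative changes for subjects whose baseline approaches zero; with
#' `c = 0` this is ordinary percent change from baseline.
#'
#' @param y_t Concentration at a post-test timepoint.
#' @param y_0 Concentration at t0 (same day).
#' @param c_shift Shift constant in concentration units (see
#'   [select_shift_constant()]).
#' @return The relative change in percent.
#' @examples
#' relative_change(6, 4, 4)    # 25
#' relative_change(130, 100, 0)  # 30
#' @export
relative_change <- function(y_t, y_0, c_shift = 0) {
  if (any(y_0 + c_shift <= 0, na.rm = TRUE)) {
    abort("`y_0 + c_shift` must be positive.",
          class = "mechmarker_domain_error")
  }
  (y_t - y_0) / (y_0 + c_shift) * 100
}

#' Select the denominator shift constant for relative changes
#'
#' Returns the smallest `c >= 0` such that no relative change
#' `(y_t - y_0)/(y_0 + c) * 100` at the capped timepoints (t1 and t2 by
#' default), over all subjects and load levels of the marker, exceeds `cap`
#' percent. Closed form: over records with `y_t > y_0`,
#' `c = max(0, max((y_t - y_0) * 100 / cap - y_0))`. The cap constrains the
#' maximal positive change (the responses of interest are increases); one
#' constant is selected per marker, pooled over subjects and loads.
#'
#' @param panel Duplicate-averaged marker-panel tibble containing t0 and the
#'   capped timepoints for the marker.
#' @param marker Marker label.
#' @param cap Cap on the maximal relative change, in percent (default 75).
#' @param cap_timepoints Timepoints whose changes are constrained
#'   (default t1, t2; the late timepoint is deliberately unconstrained).
#' @return The shift constant `c` (concentration units). If no record has a
#'   positive change, 0 with a warning.
#' @examples
#' panel <- tibble::tibble(
#'   subject_id = 1, marker = "IL-6", load_code = 0,
#'   timepoint = c("t0", "t1"), concentration = c(2, 4)
#' )
#' select_shift_constant(panel, "IL-6")  # 2/0.75 - 2
#' @export
select_shift_constant <- function(panel, marker, cap = 75,
                                  cap_timepoints = c("t1", "t2")) {
  check_panel(panel)
  if (cap <= 0) {
    abort("`cap` must be positive.", class = "mechmarker_domain_error")
  }
  paired <- pair_with_baseline(panel, marker, cap_timepoints)
  rising <- paired %>% filter(.data$y_t > .data$y_0)
  if (nrow(rising) == 0) {
    warn(paste0("No positive change records for ", marker,
                " at the capped timepoints; shift constant set to 0."))
    return(0)
  }
  max(0, max((rising$y_t - rising$y_0) * 100 / cap - rising$y_0))
}

# Pair post-test concentrations with the same-day (same load) t0 value.
pair_with_baseline <- function(panel, marker, timepoints) {
  slice <- panel %>% filter(.data$marker == !!marker)
  base <- slice %>%
    filter(.data$timepoint == "t0") %>%
    select("subject_id", "load_code", y_0 = "concentration")
  slice %>%
    filter(.data$timepoint %in% timepoints) %>%
    select("subject_id", "load_code", "timepoint", y_t = "concentration") %>%
    dplyr::inner_join(base, by = c("subject_id", "load_code"))
}

#' Build the change table for the analysis
#'
#' Turns a duplicate-averaged concentration panel into per-subject change
#' values `delta` for the post-test timepoints against the same-day t0
#' value, on either the absolute scale (normalized by the pooled baseline
#' median, see [absolute_change()]) or the shifted relative scale (see
#' [relative_change()] and [select_shift_constant()]). On the absolute
#' scale, markers listed in `log_markers` are `log10(1 + x)`-transformed
#' first (ADAMTS-4 by default).
#'
#' @param panel Duplicate-averaged marker-panel tibble.
#' @param scale `"relative"` or `"absolute"`.
#' @param markers Markers to transform; defaults to all in the panel.
#' @param cap,cap_timepoints Passed to [select_shift_constant()] (relative
#'   scale).
#' @param log_markers Markers log-transformed before the absolute change.
#' @param timepoints Post-test timepoints to emit (default t1-t3).
#' @return A change-table tibble: `subject_id`, `marker`, `load_code`,
#'   `timepoint`, `delta`, `scale`, and the per-marker constant used
#'   (`shift_c` or `baseline_median_m`). (subject, load) pairs lacking a t0
#'   record are skipped with a message.
#' @examples
#' cfg <- sim_config(n_subjects = 3, seed = 2)
#' panel <- average_duplicates(simulate_concentration_panel(cfg))
#' build_change_table(panel, scale = "relative")
#' @export
build_change_table <- function(panel, scale = c("relative", "absolute"),
                               markers = NULL, cap = 75,
                               cap_timepoints = c("t1", "t2"),
                               log_markers = "ADAMTS-4",
                               timepoints = post_timepoints()) {
  scale <- match.arg(scale)
  check_panel(panel)
  if ("replicate" %in% names(panel)) {
    abort("Change table must be built from a duplicate-averaged panel.",
          class = "mechmarker_input_error")
  }
  if (is.null(markers)) markers <- unique(panel$marker)
  out <- purrr::map(markers, function(mk) {
    pl <- panel
    if (scale == "absolute" && mk %in% log_markers) {
      pl <- log_transform_marker(pl, mk)
    }
    paired <- pair_with_baseline(pl, mk, timepoints)
    n_post <- sum(pl$marker == mk & pl$timepoint %in% timepoints)
    if (nrow(paired) < n_post) {
      inform(paste0(n_post - nrow(paired), " record(s) of ", mk,
                    " skipped: no t0 value for their (subject, load)."))
    }
    if (nrow(paired) == 0) {
      inform(paste0("No change records computable for ", mk,
                    " (no post-test concentration with a matching t0)."))
      return(NULL)
    }
    if (scale == "relative") {
      c_shift <- select_shift_constant(pl, mk, cap = cap,
                                       cap_timepoints = cap_timepoints)
      paired %>%
        mutate(marker = mk,
               delta = relative_change(.data$y_t, .data$y_0, c_shift),
               scale = "relative", shift_c = c_shift)
    } else {
      m <- baseline_median(pl, mk)
      paired %>%
        mutate(marker = mk,
               delta = absolute_change(.data$y_t, .data$y_0, m),
               scale = "absolute", baseline_median_m = m)
    }
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(subject_id = integer(), marker = character(),
                  load_code = integer(), timepoint = character(),
                  delta = numeric(), scale = character()))
  }
  out %>%
    select(-"y_t", -"y_0") %>%
    dplyr::relocate("subject_id", "marker", "load_code", "timepoint",
                    "delta", "scale")
}
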