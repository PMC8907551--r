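# Shared column checks for long-format marker panels.
check_panel <- function(panel, need_replicate = FALSE) {
  need <- c("subject_id", "marker", "load_code", "timepoint", "concentration")
  if (need_replicate) need <- c(need, "replicate")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols) > 0) {
    abort(paste0("Panel lacks column(s) ",
                 paste0("`", missing_cols, "`", collapse = ", "), "."),
          class = "mechmarker_input_error")
  }
  invisible(panel)
}

panel_key <- function(panel) {
  paste(panel$subject_id, panel$marker, panel$load_code, panel$timepoint,
        sep = "\r")
}

#' Average duplicate assay measurements
#'
#' Collapses replicate ELISA measurements to their arithmetic mean, one
#' record per (subject, marker, load, timepoint). An `out_of_range` flag on
#' any replicate propagates to the averaged record.
#'
#' @param panel Marker-panel tibble with a `replicate` column (1 or 2
#'   replicates per key).
#' @return The panel without the `replicate` column, one row per key.
#'   Idempotent: a panel without `replicate` is returned unchanged (after
#'   validation).
#' @examples
#' cfg <- sim_config(n_subjects = 2, seed = 3)
#' panel <- simulate_concentration_panel(cfg)
#' average_duplicates(panel)
#' @export
average_duplicates <- function(panel) {
  check_panel(panel)
  if (!"replicate" %in% names(panel)) {
    return(panel)
  }
  counts <- table(panel_key(panel))
  if (any(counts > 2)) {
    k <- strsplit(names(counts)[which(counts > 2)[1]], "\r", fixed = TRUE)[[1]]
    abort(paste0("More than 2 replicates for key (subject ", k[1],
                 ", marker ", k[2], ", load ", k[3], ", timepoint ", k[4], ")."),
          class = "mechmarker_integrity_error")
  }
  has_flag <- "out_of_range" %in% names(panel)
  out <- panel %>%
    group_by(across(-all_of(c("replicate", "concentration",
                              if (has_flag) "out_of_range")))) %>%
    summarise(
      concentration = mean(.data$concentration),
      out_of_range = if (has_flag) any(.data$out_of_range) else FALSE,
      .groups = "drop"
    )
  if (!has_flag) out$out_of_range <- NULL
  out
}

#' Intra-assay coefficient of variation from duplicates
#'
#' Per duplicate pair the CV is the two-point sample standard deviation,
#' `|x1 - x2| / sqrt(2)`, divided by the pair mean, in percent. Returned per
#' marker as the mean and SD of the record-level CVs, the standard precision
#' summary for ELISA duplicates.
#'
#' @param panel Marker-panel tibble with `replicate` column.
#' @return A tibble per marker: `n_pairs`, `cv_mean`, `cv_sd` (in %),
#'   `n_skipped` (pairs with zero mean, which have no defined CV). Skipped
#'   pairs are also reported via a message.
#' @examples
#' panel <- tibble::tibble(
#'   subject_id = 1, marker = "COMP", load_code = 0, timepoint = "t0",
#'   replicate = c(1, 2), concentration = c(98, 102)
#' )
#' intra_assay_cv(panel)
#' @export
intra_assay_cv <- function(panel) {
  check_panel(panel, need_replicate = TRUE)
  pairs <- panel %>%
    group_by(.data$subject_id, .data$marker, .data$load_code, .data$timepoint) %>%
    summarise(n_rep = dplyr::n(),
              pair_mean = mean(.data$concentration),
              pair_sd = sd(.data$concentration),
              .groups = "drop") %>%
    filter(.data$n_rep == 2)
  skipped <- pairs %>% filter(.data$pair_mean == 0)
  if (nrow(skipped) > 0) {
    inform(paste0(nrow(skipped),
                  " duplicate pair(s) with zero mean skipped in CV computation."))
  }
  pairs %>%
    filter(.data$pair_mean != 0) %>%
    mutate(cv = 100 * .data$pair_sd / .data$pair_mean) %>%
    group_by(.data$marker) %>%
    summarise(n_pairs = dplyr::n(),
              cv_mean = mean(.data$cv),
              cv_sd = sd(.data$cv),
              .groups = "drop") %>%
    left_join(skipped %>% dplyr::count(.data$marker, name = "n_skipped"),
              by = "marker") %>%
    mutate(n_skipped = dplyr::coalesce(.data$n_skipped, 0L))
}

#' Add the synthesis/degradation ratio marker
#'
#' Appends CPII/C2C records (type II collagen synthesis over degradation) to
#' a duplicate-averaged panel: for every key at which both CPII and C2C are
#' present, the ratio of their concentrations. Keys with a zero C2C value are
#' skipped with a warning.
#'
#' @param panel Duplicate-averaged marker-panel tibble containing CPII and
#'   C2C records.
#' @param ratio_name Label for the derived marker (default "CPII/C2C").
#' @return The panel with the ratio records appended.
#' @examples
#' panel <- tibble::tibble(
#'   subject_id = 1, marker = c("CPII", "C2C"), load_code = 0,
#'   timepoint = "t0", concentration = c(400, 200)
#' )
#' add_ratio_marker(panel)
#' @export
add_ratio_marker <- function(panel, ratio_name = "CPII/C2C") {
  check_panel(panel)
  if ("replicate" %in% names(panel)) {
    abort("Ratio marker must be computed on a duplicate-averaged panel.",
          class = "mechmarker_input_error")
  }
  key_cols <- intersect(c("subject_id", "load_pct", "load_code", "timepoint"),
                        names(panel))
  wide <- panel %>%
    filter(.data$marker %in% c("CPII", "C2C")) %>%
    select(all_of(key_cols), "marker", "concentration") %>%
    tidyr::pivot_wider(names_from = "marker", values_from = "concentration")
  if (!all(c("CPII", "C2C") %in% names(wide))) {
    warn("CPII or C2C absent from panel; no ratio records added.")
    return(panel)
  }
  wide <- wide %>% filter(!is.na(.data$CPII), !is.na(.data$C2C))
  zero <- wide %>% filter(.data$C2C == 0)
  if (nrow(zero) > 0) {
    warn(paste0(nrow(zero), " key(s) with C2C = 0 skipped for the ratio marker."))
  }
  ratio <- wide %>%
    filter(.data$C2C != 0) %>%
    mutate(marker = ratio_name, concentration = .data$CPII / .data$C2C) %>%
    select(-"CPII", -"C2C")
  if ("out_of_range" %in% names(panel)) ratio$out_of_range <- FALSE
  dplyr::bind_rows(panel, ratio)
}

#' Log-transform one marker's concentrations
#'
#' Replaces the named marker's concentrations by `log10(1 + x)`, the
#' variance-stabilizing transform used for markers whose raw values span
#' orders of magnitude (ADAMTS-4 by default in the analysis pipeline) before
#' absolute changes are computed.
#'
#' @param panel Marker-panel tibble.
#' @param marker Marker label to transform.
#' @return The panel with the transformed concentrations.
#' @examples
#' panel <- tibble::tibble(
#'   subject_id = 1, marker = "ADAMTS-4", load_code = 0,
#'   timepoint = "t0", concentration = 99
#' )
#' log_transform_marker(panel, "ADAMTS-4")$concentration  # 2
#' @export
log_transform_marker <- function(panel, marker) {
  check_panel(panel)
  sel <- panel$marker == marker
  if (any(panel$concentration[sel] < 0, na.rm = TRUE)) {
    abort("log10(1 + x) requires nonnegative concentrations.",
          class = "mechmarker_domain_error")
  }
  panel$concentration[sel] <- log10(1 + panel$concentration[sel])
  panel
}

#' Exclude subject/marker combinations
#'
#' Removes records by explicit (subject, marker) rules and/or by a
#' detection-limit rule (a subject is dropped for a marker when at least
#' `min_flagged` of their records for that marker are flagged
#' `out_of_range`). This mirrors the handling of subjects whose values for
#' one marker fall outside the assay's detection limits; records of other
#' markers for the same subject are never touched.
#'
#' @param panel Marker-panel tibble.
#' @param rules Tibble with columns `subject_id`, `marker` (explicit
#'   exclusions), or `NULL`.
#' @param detection_limit_rule If `TRUE`, also exclude per (subject, marker)
#'   when flagged records reach `min_flagged`.
#' @param min_flagged Flag count triggering the detection-limit rule.
#' @return A list with `panel` (filtered) and `report` (one row per removed
#'   (subject, marker): the triggering rule and the number of records
#'   removed).
#' @examples
#' cfg <- sim_config(n_subjects = 2, seed = 5)
#' panel <- average_duplicates(simulate_concentration_panel(cfg))
#' rules <- tibble::tibble(subject_id = 101L, marker = "ADAMTS-4")
#' res <- exclude_subjects(panel, rules)
#' res$report
#' @export
exclude_subjects <- function(panel, rules = NULL,
                             detection_limit_rule = FALSE, min_flagged = 1L) {
  check_panel(panel)
  report <- tibble(subject_id = panel$subject_id[0], marker = character(),
                   rule = character(), n_records = integer())
  drop <- rep(FALSE, nrow(panel))
  if (!is.null(rules) && nrow(rules) > 0) {
    for (r in seq_len(nrow(rules))) {
      hit <- panel$subject_id == rules$subject_id[r] &
        panel$marker == rules$marker[r]
      if (any(hit)) {
        report <- dplyr::bind_rows(report, tibble(
          subject_id = rules$subject_id[r], marker = rules$marker[r],
          rule = "explicit", n_records = sum(hit)
        ))
      }
      drop <- drop | hit
    }
  }
  if (detection_limit_rule && "out_of_range" %in% names(panel)) {
    flagged <- panel %>%
      filter(.data$out_of_range) %>%
      dplyr::count(.data$subject_id, .data$marker) %>%
      filter(.data$n >= min_flagged)
    for (r in seq_len(nrow(flagged))) {
      hit <- panel$subject_id == flagged$subject_id[r] &
        panel$marker == flagged$marker[r]
      if (any(hit & !drop)) {
        report <- dplyr::bind_rows(report, tibble(
          subject_id = flagged$subject_id[r], marker = flagged$marker[r],
          rule = "detection_limit", n_records = sum(hit & !drop)
        ))
      }
      drop <- drop | hit
    }
  }
  list(panel = panel[!drop, , drop = FALSE], report = report)
}

#' Pooled baseline median for a marker
#'
#' The median of all raw t0 (immediately pre-test) measurements for the
#' marker, pooled over subjects and load conditions. This is the normalizing
#' constant `m` of the absolute change scale, making five change points mean
#' a change of 5% of the marker's typical baseline level.
#'
#' @param panel Marker-panel tibble (duplicate-averaged or not; all t0 rows
#'   enter the pool).
#' @param marker Marker label.
#' @return The median concentration (marker units).
#' @examples
#' panel <- tibble::tibble(
#'   subject_id = 1:3, marker = "COMP", load_code = 0,
#'   timepoint = "t0", concentration = c(1, 2, 3)
#' )
#' baseline_median(panel, "COMP")  # 2
#' @export
baseline_median <- function(panel, marker) {
  check_panel(panel)
  vals <- panel$concentration[panel$marker == marker & panel$timepoint == "t0"]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    abort(paste0("No t0 records for marker ", marker, "."),
          class = "mechmarker_integrity_error")
  }
  median(vals)
}
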