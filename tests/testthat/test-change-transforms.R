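test_that("absolute change is normalized by the baseline median", {
  expect_equal(absolute_change(105, 100, 100), 5)
  expect_equal(absolute_change(42, 42, 7), 0)
  expect_equal(absolute_change(450, 400, 500), 10)
  # invariant under common rescaling of all three quantities
  expect_equal(absolute_change(450 * 3, 400 * 3, 500 * 3),
               absolute_change(450, 400, 500))
  expect_error(absolute_change(1, 1, 0), class = "mechmarker_domain_error")
})

test_that("relative change reduces to percent change at zero shift", {
  expect_equal(relative_change(6, 4, 4), 25)
  expect_equal(relative_change(5, 5, 2), 0)
  expect_equal(relative_change(130, 100, 0), 30)
  expect_error(relative_change(1, 0, 0), class = "mechmarker_domain_error")
  # strictly decreasing in c for increases, increasing for decreases
  cs <- c(0, 1, 5, 20)
  expect_true(all(diff(relative_change(10, 5, cs)) < 0))
  expect_true(all(diff(relative_change(2, 5, cs)) > 0))
})

ct_panel <- function(...) {
  rows <- list(...)
  tibble::tibble(
    subject_id = vapply(rows, `[[`, numeric(1), 1),
    marker = "IL-6",
    load_code = 0L,
    timepoint = vapply(rows, `[[`, character(1), 2),
    concentration = vapply(rows, `[[`, numeric(1), 3)
  )
}

test_that("shift-constant selection caps the maximal t1/t2 change exactly", {
  # single record: invert the cap equation
  p1 <- ct_panel(list(1, "t0", 2), list(1, "t1", 4))
  c1 <- select_shift_constant(p1, "IL-6")
  expect_equal(c1, 2 / 0.75 - 2, tolerance = 1e-12)
  expect_equal(relative_change(4, 2, c1), 75)
  # cap not binding: c = 0
  p2 <- ct_panel(list(1, "t0", 10), list(1, "t1", 12))
  expect_equal(select_shift_constant(p2, "IL-6"), 0)
  # the binding record maximizes the closed form
  p3 <- ct_panel(list(1, "t0", 10), list(1, "t1", 12),
                 list(2, "t0", 4), list(2, "t1", 9))
  expect_equal(select_shift_constant(p3, "IL-6"), 5 / 0.75 - 4,
               tolerance = 1e-12)
  # t3 changes are deliberately unconstrained
  p4 <- ct_panel(list(1, "t0", 2), list(1, "t3", 40))
  expect_warning(c4 <- select_shift_constant(p4, "IL-6"), "shift constant")
  expect_equal(c4, 0)
})

test_that("cap property holds on a simulated panel with the cap attained", {
  cfg <- sim_config(n_subjects = 12, seed = 31)
  panel <- average_duplicates(simulate_concentration_panel(cfg))
  for (mk in c("IL-6", "MMP-3")) {
    c_mk <- select_shift_constant(panel, mk)
    changes <- build_change_table(panel, "relative", markers = mk)
    t12 <- changes$delta[changes$timepoint %in% c("t1", "t2")]
    expect_lte(max(t12), 75 + 1e-9)
    if (c_mk > 0) {
      expect_equal(max(t12), 75, tolerance = 1e-9)  # binding record attains it
    }
  }
})

# reconstruct the generator's injected change values for one marker from
# the panel's own t0/t1 concentrations (zero assay noise, zero shift)
simulate_change_values_for_panel_check <- function(cfg, marker) {
  panel <- average_duplicates(simulate_concentration_panel(cfg))
  base <- panel[panel$marker == marker & panel$timepoint == "t0",
                c("subject_id", "load_code", "concentration")]
  t1 <- panel[panel$marker == marker & panel$timepoint == "t1",
              c("subject_id", "load_code", "concentration")]
  joined <- dplyr::inner_join(base, t1, by = c("subject_id", "load_code"),
                              suffix = c("_0", "_1"))
  joined$delta_true <- (joined$concentration_1 - joined$concentration_0) /
    joined$concentration_0 * 100
  joined[c("subject_id", "load_code", "delta_true")]
}

test_that("change tables round-trip the generating delta structure", {
  # noise-free generator (all SDs and assay CV zero): the relative-change
  # transform must recover the injected response exactly, scaled by the
  # per-timepoint decay profile
  mk <- default_marker_spec()
  mk$cv_intra <- 0
  mk[mk$marker == "COMP", c("mu_alpha", "sd_alpha", "mu_beta", "sd_beta",
                            "sd_error")] <- list(10, 0, 3, 0, 0)
  cfg <- sim_config(n_subjects = 6, markers = mk, seed = 13,
                    timepoint_profile = c(t1 = 1, t2 = 0.5, t3 = 0.2))
  panel <- average_duplicates(simulate_concentration_panel(cfg))
  changes <- build_change_table(panel, "relative", markers = "COMP")
  for (tp in c("t1", "t2", "t3")) {
    prof <- c(t1 = 1, t2 = 0.5, t3 = 0.2)[[tp]]
    slice <- changes[changes$timepoint == tp, ]
    expect_equal(slice$delta, prof * (10 + 3 * slice$load_code),
                 tolerance = 1e-8)
  }
  expect_true(all(changes$shift_c == 0))  # cap not binding at these levels
})

test_that("degenerate panels yield empty or zero change tables", {
  # t0 only: nothing to compute, skipped keys are logged
  p0 <- ct_panel(list(1, "t0", 5), list(2, "t0", 6))
  expect_message(ch0 <- build_change_table(p0, "relative"),
                 "No change records")
  expect_equal(nrow(ch0), 0)
  # constant concentrations: all deltas 0 on both scales
  pc <- ct_panel(list(1, "t0", 5), list(1, "t1", 5), list(1, "t2", 5),
                 list(2, "t0", 8), list(2, "t1", 8), list(2, "t2", 8))
  suppressWarnings({
    rel <- build_change_table(pc, "relative")
    abs_ <- build_change_table(pc, "absolute", log_markers = character(0))
  })
  expect_true(all(rel$delta == 0))
  expect_true(all(abs_$delta == 0))
})
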