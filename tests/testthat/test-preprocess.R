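panel_row <- function(subject_id = 1L, marker = "COMP", load_code = 0L,
                      timepoint = "t0", replicate = 1L, concentration = 1,
                      out_of_range = FALSE) {
  tibble::tibble(subject_id = subject_id, marker = marker,
                 load_code = load_code, timepoint = timepoint,
                 replicate = replicate, concentration = concentration,
                 out_of_range = out_of_range)
}

test_that("duplicate averaging takes the arithmetic mean and is idempotent", {
  panel <- dplyr::bind_rows(
    panel_row(replicate = 1L, concentration = 98),
    panel_row(replicate = 2L, concentration = 102),
    panel_row(marker = "MMP-3", replicate = 1L, concentration = 50),
    panel_row(marker = "IL-6", replicate = 1L, concentration = 4),
    panel_row(marker = "IL-6", replicate = 2L, concentration = 5)
  )
  avg <- average_duplicates(panel)
  expect_equal(avg$concentration[avg$marker == "COMP"], 100)
  expect_equal(avg$concentration[avg$marker == "MMP-3"], 50)
  expect_equal(avg$concentration[avg$marker == "IL-6"], 4.5)
  expect_identical(average_duplicates(avg), avg)
  # a flagged replicate propagates to the averaged record
  flagged <- dplyr::bind_rows(
    panel_row(replicate = 1L, concentration = 1, out_of_range = TRUE),
    panel_row(replicate = 2L, concentration = 3)
  )
  expect_true(average_duplicates(flagged)$out_of_range)
  # more than two replicates violates the assay layout
  bad <- dplyr::bind_rows(panel_row(replicate = 1L), panel_row(replicate = 2L),
                          panel_row(replicate = 3L))
  expect_error(average_duplicates(bad), class = "mechmarker_integrity_error")
})

test_that("intra-assay CV uses the two-point sample SD over the pair mean", {
  panel <- dplyr::bind_rows(
    panel_row(replicate = 1L, concentration = 98),
    panel_row(replicate = 2L, concentration = 102),
    panel_row(marker = "MMP-3", replicate = 1L, concentration = 7),
    panel_row(marker = "MMP-3", replicate = 2L, concentration = 7),
    panel_row(marker = "IL-6", replicate = 1L, concentration = 10),
    panel_row(marker = "IL-6", replicate = 2L, concentration = 30)
  )
  cv <- intra_assay_cv(panel)
  expect_equal(cv$cv_mean[cv$marker == "COMP"], 100 * (4 / sqrt(2)) / 100,
               tolerance = 1e-10)
  expect_equal(cv$cv_mean[cv$marker == "MMP-3"], 0)
  expect_equal(cv$cv_mean[cv$marker == "IL-6"], 100 * (20 / sqrt(2)) / 20,
               tolerance = 1e-10)
  # zero-mean pairs are skipped and counted
  zero <- dplyr::bind_rows(
    panel_row(marker = "C2C", replicate = 1L, concentration = 0),
    panel_row(marker = "C2C", replicate = 2L, concentration = 0)
  )
  expect_message(cv0 <- intra_assay_cv(dplyr::bind_rows(panel, zero)),
                 "zero mean")
  expect_false("C2C" %in% cv0$marker[!is.na(cv0$cv_mean)] &&
                 cv0$n_skipped[cv0$marker == "C2C"] == 0)
})

test_that("the synthesis/degradation ratio marker divides CPII by C2C", {
  panel <- average_duplicates(dplyr::bind_rows(
    panel_row(marker = "CPII", concentration = 400),
    panel_row(marker = "C2C", concentration = 200),
    panel_row(marker = "CPII", timepoint = "t1", concentration = 300),
    panel_row(marker = "C2C", timepoint = "t1", concentration = 300)
  ))
  with_ratio <- add_ratio_marker(panel)
  ratio <- with_ratio[with_ratio$marker == "CPII/C2C", ]
  expect_equal(ratio$concentration[ratio$timepoint == "t0"], 2)
  expect_equal(ratio$concentration[ratio$timepoint == "t1"], 1)
  # missing C2C at a key: no ratio record, warning raised
  partial <- average_duplicates(panel_row(marker = "CPII", concentration = 10))
  expect_warning(out <- add_ratio_marker(partial), "absent")
  expect_false("CPII/C2C" %in% out$marker)
  # zero C2C denominator skipped with warning
  zero <- average_duplicates(dplyr::bind_rows(
    panel_row(marker = "CPII", concentration = 5),
    panel_row(marker = "C2C", concentration = 0)
  ))
  expect_warning(out0 <- add_ratio_marker(zero), "C2C = 0")
  expect_false("CPII/C2C" %in% out0$marker)
})

test_that("log10(1+x) transform hits only the named marker", {
  panel <- average_duplicates(dplyr::bind_rows(
    panel_row(marker = "ADAMTS-4", concentration = 0),
    panel_row(marker = "ADAMTS-4", timepoint = "t1", concentration = 9),
    panel_row(marker = "ADAMTS-4", timepoint = "t2", concentration = 99),
    panel_row(marker = "COMP", concentration = 99)
  ))
  out <- log_transform_marker(panel, "ADAMTS-4")
  tr <- out[out$marker == "ADAMTS-4", ]
  expect_equal(sort(tr$concentration), c(0, 1, 2))
  expect_equal(out$concentration[out$marker == "COMP"], 99)
  neg <- panel_row(marker = "ADAMTS-4", concentration = -1)
  expect_error(log_transform_marker(neg, "ADAMTS-4"),
               class = "mechmarker_domain_error")
})

test_that("exclusions remove only the targeted marker records", {
  cfg <- sim_config(n_subjects = 4, seed = 8)
  panel <- average_duplicates(simulate_concentration_panel(cfg))
  rules <- tibble::tibble(subject_id = 101L, marker = "ADAMTS-4")
  res <- exclude_subjects(panel, rules)
  expect_false(any(res$panel$subject_id == 101 &
                     res$panel$marker == "ADAMTS-4"))
  # other markers of the excluded subject stay
  expect_true(any(res$panel$subject_id == 101 & res$panel$marker == "COMP"))
  expect_equal(nrow(res$report), 1)
  expect_equal(res$report$rule, "explicit")
  expect_equal(res$report$n_records,
               sum(panel$subject_id == 101 & panel$marker == "ADAMTS-4"))
  # empty rules are a no-op
  expect_identical(exclude_subjects(panel)$panel, panel)
  # detection-limit rule drops a subject/marker with flagged records
  panel$out_of_range[panel$subject_id == 102 & panel$marker == "MMP-9"][1:3] <- TRUE
  res2 <- exclude_subjects(panel, detection_limit_rule = TRUE)
  expect_false(any(res2$panel$subject_id == 102 & res2$panel$marker == "MMP-9"))
  expect_true(any(res2$report$rule == "detection_limit"))
})

test_that("baseline median pools t0 values and ignores record order", {
  p1 <- dplyr::bind_rows(
    panel_row(subject_id = 1L, concentration = 1),
    panel_row(subject_id = 2L, concentration = 2),
    panel_row(subject_id = 3L, concentration = 3),
    panel_row(subject_id = 1L, timepoint = "t1", concentration = 100)
  )
  expect_equal(baseline_median(p1, "COMP"), 2)
  p2 <- dplyr::bind_rows(
    panel_row(subject_id = 1L, concentration = 10),
    panel_row(subject_id = 2L, concentration = 20),
    panel_row(subject_id = 3L, concentration = 30),
    panel_row(subject_id = 4L, concentration = 40)
  )
  expect_equal(baseline_median(p2, "COMP"), 25)
  expect_equal(baseline_median(panel_row(concentration = 7), "COMP"), 7)
  # order invariance and invariance to duplicating the whole table
  shuffled <- p2[sample(nrow(p2)), ]
  expect_equal(baseline_median(shuffled, "COMP"), 25)
  expect_equal(baseline_median(dplyr::bind_rows(p2, p2), "COMP"), 25)
  expect_error(baseline_median(p2, "IL-6"),
               class = "mechmarker_integrity_error")
})
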