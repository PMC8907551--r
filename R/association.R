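#' Per-individual dose-response slopes
#'
#' For every subject x marker x timepoint (x scale), the OLS slope of the
#' change value on the coded load level — the slope of a regression line
#' through the subject's points at the three ambulatory loads. With the
#' complete coded loads \{-1, 0, +1\} this equals
#' `(delta(+1) - delta(-1)) / 2` exactly.
#'
#' @param changes Change-table tibble with `subject_id`, `load_code`,
#'   `delta` and optional `marker`, `timepoint`, `scale` columns.
#' @return A tibble with one row per subject and slice: `slope` (change
#'   points per load level) and `n_loads`. Subjects with fewer than 2 load
#'   levels are skipped with a message.
#' @examples
#' changes <- tibble::tibble(subject_id = 1, load_code = c(-1, 0, 1),
#'                           delta = c(0, 5, 10))
#' individual_slopes(changes)
#' @export
individual_slopes <- function(changes) {
  need <- c("subject_id", "load_code", "delta")
  stopifnot(all(need %in% names(changes)))
  keys <- intersect(c("subject_id", "marker", "timepoint", "scale"),
                    names(changes))
  out <- changes %>%
    group_by(across(all_of(keys))) %>%
    summarise(
      n_loads = dplyr::n_distinct(.data$load_code),
      slope = if (dplyr::n_distinct(.data$load_code) >= 2) {
        unname(coef(lm(delta ~ load_code,
                       data = data.frame(delta = .data$delta,
                                         load_code = .data$load_code)))[2])
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  skipped <- sum(is.na(out$slope))
  if (skipped > 0) {
    inform(paste0(skipped, " subject-slice(s) skipped: fewer than 2 load levels."))
    out <- out %>% filter(!is.na(.data$slope))
  }
  out
}

#' Load-averaged Spearman correlation of two change variables
#'
#' The crossover design yields, for each pair of change variables, three
#' within-load-level series over the same subjects. The summary correlation
#' is the Spearman correlation computed at each load level (over
#' pairwise-complete subjects, midranks for ties) and then averaged over
#' the load levels; conditioning on load removes the load effect before
#' correlating.
#'
#' @param a,b Change-table slices with columns `subject_id`, `load_code`,
#'   `delta` (one marker x timepoint each).
#' @param min_pairs Minimum complete pairs per load level (levels below
#'   this are dropped with a warning; if all are dropped, an error).
#' @return The averaged Spearman correlation in \[-1, 1\].
#' @examples
#' a <- tibble::tibble(subject_id = rep(1:5, 3),
#'                     load_code = rep(c(-1, 0, 1), each = 5),
#'                     delta = rnorm(15))
#' average_spearman(a, a)  # 1
#' @export
average_spearman <- function(a, b, min_pairs = 3L) {
  joined <- join_change_pair(a, b)
  per_load <- joined %>%
    group_by(.data$load_code) %>%
    summarise(n = sum(complete.cases(.data$delta_a, .data$delta_b)),
              rho = if (sum(complete.cases(.data$delta_a, .data$delta_b)) >=
                          min_pairs) {
                cor(.data$delta_a, .data$delta_b, method = "spearman",
                    use = "pairwise.complete.obs")
              } else {
                NA_real_
              },
              .groups = "drop")
  dropped <- per_load %>% filter(is.na(.data$rho))
  if (nrow(dropped) > 0) {
    warn(paste0("Load level(s) ", paste(dropped$load_code, collapse = ", "),
                " dropped: fewer than ", min_pairs, " complete pairs."))
  }
  kept <- per_load$rho[!is.na(per_load$rho)]
  if (length(kept) == 0) {
    abort("Correlation undefined: no load level has enough complete pairs.",
          class = "mechmarker_correlation_error")
  }
  mean(kept)
}

join_change_pair <- function(a, b) {
  need <- c("subject_id", "load_code", "delta")
  stopifnot(all(need %in% names(a)), all(need %in% names(b)))
  dplyr::inner_join(
    a %>% select(all_of(need)) %>% rename(delta_a = "delta"),
    b %>% select(all_of(need)) %>% rename(delta_b = "delta"),
    by = c("subject_id", "load_code")
  )
}

#' Bootstrap Fisher-z inference for the averaged Spearman correlation
#'
#' Resamples subjects with replacement (each subject's full load profile
#' kept intact, respecting within-subject dependence), recomputes the
#' load-averaged Spearman correlation per replicate, and forms a 95%
#' confidence interval and two-sided p-value via a normal approximation on
#' the Fisher z (atanh) scale, back-transforming the interval with tanh.
#' Degenerate resamples (undefined correlation) are redrawn up to a retry
#' cap and counted.
#'
#' @inheritParams average_spearman
#' @param n_boot Bootstrap replicates (>= 200; default 2000).
#' @param seed Integer seed (required: bootstrap inference must be
#'   reproducible).
#' @param level Confidence level.
#' @param retry_cap Redraw attempts per degenerate replicate.
#' @return A one-row tibble: `kind`, `rho`, `conf.low`, `conf.high`,
#'   `p.value`, `n_boot`, `n_subjects`, `n_degenerate`.
#' @export
bootstrap_correlation_inference <- function(a, b, n_boot = 2000L, seed,
                                            level = 0.95, retry_cap = 50L) {
  if (n_boot < 200) {
    abort("`n_boot` must be at least 200.", class = "mechmarker_input_error")
  }
  rho_obs <- average_spearman(a, b)
  subjects <- intersect(unique(a$subject_id), unique(b$subject_id))
  n <- length(subjects)
  z_boot <- numeric(n_boot)
  n_degenerate <- 0L
  with_seed_local(seed, {
    for (i in seq_len(n_boot)) {
      rho_b <- NA_real_
      for (try in seq_len(retry_cap)) {
        draw <- sample(subjects, n, replace = TRUE)
        # resampled subjects get fresh ids so duplicates stay distinct
        a_b <- resample_subjects(a, draw)
        b_b <- resample_subjects(b, draw)
        rho_try <- tryCatch(
          suppressWarnings(average_spearman(a_b, b_b)),
          error = function(e) NA_real_
        )
        if (!is.na(rho_try)) {
          rho_b <- rho_try
          if (try > 1L) n_degenerate <- n_degenerate + (try - 1L)
          break
        }
      }
      if (is.na(rho_b)) {
        abort("Bootstrap failed: degenerate resamples exceeded the retry cap.",
              class = "mechmarker_correlation_error")
      }
      z_boot[i] <- atanh(max(-1 + 1e-9, min(1 - 1e-9, rho_b)))
    }
  })
  z_obs <- atanh(max(-1 + 1e-9, min(1 - 1e-9, rho_obs)))
  se_z <- sd(z_boot)
  zq <- qnorm(1 - (1 - level) / 2)
  if (se_z < 1e-12) {
    ci <- c(rho_obs, rho_obs)
    p <- if (abs(z_obs) < 1e-12) 1 else 0
  } else {
    ci <- tanh(z_obs + c(-1, 1) * zq * se_z)
    p <- 2 * pnorm(-abs(z_obs / se_z))
  }
  tibble(kind = "change", rho = rho_obs, conf.low = ci[1], conf.high = ci[2],
         p.value = p, n_boot = as.integer(n_boot), n_subjects = n,
         n_degenerate = n_degenerate)
}

resample_subjects <- function(tab, draw) {
  pieces <- purrr::imap(draw, function(s, idx) {
    piece <- tab[tab$subject_id == s, , drop = FALSE]
    piece$subject_id <- idx  # unique id per drawn copy
    piece
  })
  dplyr::bind_rows(pieces)
}

#' Spearman correlation of per-individual slopes
#'
#' Plain Spearman correlation, over subjects, of the individual
#' dose-response slopes of two marker x timepoint combinations, with the
#' standard asymptotic two-sided p-value.
#'
#' @param a,b Slope tibbles from [individual_slopes()] (columns
#'   `subject_id`, `slope`).
#' @return A one-row tibble: `kind`, `rho`, `p.value`, `n_subjects`.
#' @examples
#' a <- tibble::tibble(subject_id = 1:5, slope = c(1, 2, 3, 4, 5))
#' b <- tibble::tibble(subject_id = 1:5, slope = c(1, 3, 2, 5, 4))
#' slope_correlation(a, b)  # rho = 0.7
#' @export
slope_correlation <- function(a, b) {
  stopifnot(all(c("subject_id", "slope") %in% names(a)),
            all(c("subject_id", "slope") %in% names(b)))
  joined <- dplyr::inner_join(
    a %>% select("subject_id", slope_a = "slope"),
    b %>% select("subject_id", slope_b = "slope"),
    by = "subject_id"
  ) %>% filter(complete.cases(.data$slope_a, .data$slope_b))
  if (nrow(joined) < 3) {
    abort("Correlation undefined: fewer than 3 overlapping subjects.",
          class = "mechmarker_correlation_error")
  }
  ct <- suppressWarnings(
    cor.test(joined$slope_a, joined$slope_b, method = "spearman")
  )
  tibble(kind = "slope", rho = unname(ct$estimate), p.value = ct$p.value,
         n_subjects = nrow(joined))
}

#' Pairwise correlation matrices over selected combinations
#'
#' Builds the symmetric matrix of pairwise correlations between the
#' selected marker x timepoint combinations: load-averaged Spearman
#' correlations of the change values (`kind = "change"`), or plain Spearman
#' correlations of the per-individual slopes (`kind = "slope"`). Companion
#' p-value matrices come from [bootstrap_correlation_inference()] (change
#' kind, when `n_boot > 0`) or the asymptotic Spearman test (slope kind).
#'
#' @param changes Change-table tibble covering the combinations.
#' @param combos Tibble with columns `marker`, `timepoint` (defaults to all
#'   present in `changes`, e.g. the [apply_criterion_one()] selection).
#' @param kind `"change"` or `"slope"`.
#' @param n_boot Bootstrap replicates for change-kind p-values (0 skips
#'   them).
#' @param seed Seed for the bootstrap (required when `n_boot > 0`).
#' @return A `correlation_matrix` object: list with `rho` and `p` matrices
#'   (labels `"marker@timepoint"`), `kind` and `scale`.
#' @examples
#' cfg <- sim_config(n_subjects = 10, seed = 4)
#' panel <- average_duplicates(simulate_concentration_panel(cfg))
#' changes <- build_change_table(panel, "relative",
#'                               markers = c("COMP", "MMP-3"))
#' correlation_matrix(changes, kind = "slope")
#' @export
correlation_matrix <- function(changes, combos = NULL,
                               kind = c("change", "slope"),
                               n_boot = 0L, seed = NULL) {
  kind <- match.arg(kind)
  if (is.null(combos)) {
    combos <- changes %>% distinct(.data$marker, .data$timepoint)
  }
  labels <- paste0(combos$marker, "@", combos$timepoint)
  k <- nrow(combos)
  rho <- matrix(1, k, k, dimnames = list(labels, labels))
  pmat <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  slices <- purrr::map(seq_len(k), function(i) {
    changes %>% filter(.data$marker == combos$marker[i],
                       .data$timepoint == combos$timepoint[i])
  })
  slopes <- if (kind == "slope") purrr::map(slices, individual_slopes)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      if (kind == "change") {
        if (n_boot > 0) {
          if (is.null(seed)) {
            abort("`seed` is required when `n_boot > 0`.",
                  class = "mechmarker_input_error")
          }
          est <- bootstrap_correlation_inference(
            slices[[i]], slices[[j]], n_boot = n_boot,
            seed = subject_seed(seed, i * 1000L + j)
          )
          rho[i, j] <- rho[j, i] <- est$rho
          pmat[i, j] <- pmat[j, i] <- est$p.value
        } else {
          rho[i, j] <- rho[j, i] <- average_spearman(slices[[i]], slices[[j]])
        }
      } else {
        est <- slope_correlation(slopes[[i]], slopes[[j]])
        rho[i, j] <- rho[j, i] <- est$rho
        pmat[i, j] <- pmat[j, i] <- est$p.value
      }
    }
  }
  structure(list(rho = rho, p = pmat, kind = kind,
                 scale = if ("scale" %in% names(changes)) {
                   unique(changes$scale)[1]
                 } else {
                   NA_character_
                 }),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("<correlation_matrix> kind: %s, scale: %s\n", x$kind, x$scale))
  print(round(x$rho, digits))
  invisible(x)
}
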