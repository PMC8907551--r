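#' Plot change trajectories over timepoints
#'
#' Individual (thin) and mean (thick) change-from-baseline trajectories per
#' marker, stratified by load condition, over the post-test timepoints —
#' the standard visual check of the response pattern before modelling.
#'
#' @param changes Change-table tibble (one scale).
#' @param markers Optional subset of markers.
#' @return A ggplot object.
#' @export
plot_change_trajectories <- function(changes, markers = NULL) {
  if (!is.null(markers)) {
    changes <- changes %>% filter(.data$marker %in% markers)
  }
  changes <- changes %>%
    mutate(load = factor(load_pct_from_code(.data$load_code),
                         levels = load_levels()))
  means <- changes %>%
    group_by(.data$marker, .data$load, .data$timepoint) %>%
    summarise(delta = mean(.data$delta), .groups = "drop")
  ggplot2::ggplot(changes,
                  ggplot2::aes(x = .data$timepoint, y = .data$delta,
                               group = .data$subject_id)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::geom_line(data = means,
                       ggplot2::aes(group = .data$load),
                       colour = "red", linewidth = 1) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$marker),
                        cols = ggplot2::vars(.data$load),
                        scales = "free_y") +
    ggplot2::labs(x = "timepoint",
                  y = "change from baseline (points)",
                  title = "Biomarker response trajectories by load") +
    ggplot2::theme_minimal()
}

#' Heat map of a pairwise correlation matrix
#'
#' @param object A [correlation_matrix()] result.
#' @param ... Unused.
#' @return A ggplot heat map of the pairwise correlations between the
#'   selected marker x timepoint combinations.
#' @export
autoplot.correlation_matrix <- function(object, ...) {
  tab <- as_tibble(object$rho, rownames = "a") %>%
    tidyr::pivot_longer(-"a", names_to = "b", values_to = "rho") %>%
    mutate(a = factor(.data$a, levels = rownames(object$rho)),
           b = factor(.data$b, levels = rev(colnames(object$rho))))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$a, y = .data$b,
                                    fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rho)),
                       size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman",
                  title = paste0("Pairwise ", object$kind, " correlations",
                                 if (!is.na(object$scale)) {
                                   paste0(" (", object$scale, " scale)")
                                 })) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart of a Monte Carlo power table
#'
#' @param object A [run_power_study()] result (one or more scenario rows).
#' @param ... Unused.
#' @return A ggplot bar chart of the four rejection rates per scenario,
#'   with +-1 Monte Carlo standard error bars.
#' @export
autoplot.power_table <- function(object, ...) {
  long <- object %>%
    mutate(scenario = sprintf("n=%d, sd_error=%g", .data$n_subjects,
                              .data$sd_error)) %>%
    tidyr::pivot_longer(
      cols = dplyr::starts_with("power_"),
      names_to = "parameter", names_prefix = "power_",
      values_to = "power"
    ) %>%
    mutate(se = sqrt(.data$power * (1 - .data$power) / .data$n_converged),
           parameter = factor(.data$parameter,
                              levels = c("mu_alpha", "sd_alpha",
                                         "mu_beta", "sd_beta")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$parameter, y = .data$power,
                                     fill = .data$scenario)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$power - .data$se),
                   ymax = pmin(1, .data$power + .data$se)),
      position = ggplot2::position_dodge(0.8), width = 0.25
    ) +
    ggplot2::geom_hline(yintercept = 0.05, linetype = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "rejection rate at 5%",
                  title = "Monte Carlo power by model parameter") +
    ggplot2::theme_minimal()
}

#' Forest plot of response-model estimates
#'
#' @param object A [fit_response_models()] table.
#' @param part `"response"` (intercept mean/SD) or `"slope"` (slope
#'   mean/SD).
#' @param ... Unused.
#' @return A ggplot forest plot of the mean estimates with 95% CIs per
#'   marker x timepoint.
#' @export
autoplot.response_table <- function(object, part = c("response", "slope"),
                                    ...) {
  part <- match.arg(part)
  stub <- if (part == "response") "mu_alpha" else "mu_beta"
  tab <- object %>%
    mutate(combo = paste0(.data$marker, " @ ", .data$timepoint),
           est = .data[[stub]],
           lo = .data[[paste0(stub, "_low")]],
           hi = .data[[paste0(stub, "_high")]])
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$est, y = .data$combo)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$scale)) +
    ggplot2::labs(x = paste0("mean ", part, " (change points)"), y = NULL) +
    ggplot2::theme_minimal()
}
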