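#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot derived SSRT and go RT posteriors
#'
#' Group-level posterior densities of SSRT and mean go RT with the median,
#' 66% and 95% quantile intervals marked.
#'
#' @param object an `sst_derived` from [derive_outcomes()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot sst_derived
#' @export
autoplot.sst_derived <- function(object, ...) {
  draws <- dplyr::bind_rows(
    tibble::tibble(measure = "SSRT", value = as.vector(object$ssrt_draws)),
    tibble::tibble(measure = "go RT", value = as.vector(object$go_rt_draws))
  )
  gs <- object$group_summary |>
    dplyr::mutate(measure = ifelse(.data$measure == "ssrt", "SSRT", "go RT"))
  ggplot2::ggplot(draws, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80", colour = "grey30") +
    ggplot2::geom_segment(data = gs, ggplot2::aes(x = .data$q025, xend = .data$q975,
                                                  y = 0, yend = 0),
                          linewidth = 0.4) +
    ggplot2::geom_segment(data = gs, ggplot2::aes(x = .data$q17, xend = .data$q83,
                                                  y = 0, yend = 0),
                          linewidth = 1.4) +
    ggplot2::geom_point(data = gs, ggplot2::aes(x = .data$median, y = 0), size = 2) +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::labs(x = "seconds", y = "posterior density")
}

#' Plot a posterior predictive check
#'
#' Observed summary statistics (points) against the predictive median and
#' 95% quantile interval over simulated participants.
#'
#' @param object a `ppc_report` from [posterior_predictive()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ppc_report
#' @export
autoplot.ppc_report <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(label = paste(.data$trial_type, .data$response, sep = ":"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label)) +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$pred_median,
                                          ymin = .data$pred_lo,
                                          ymax = .data$pred_hi),
                             colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), colour = "red3",
                        shape = 4, size = 2.5, stroke = 1.2) +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = "value",
                  caption = "crosses: observed; ranges: posterior predictive")
}

#' Plot conditional direct and indirect effects
#'
#' The moderated direct and indirect (mediated) effects of the predictor on
#' the outcome as a function of the moderator, with percentile bootstrap
#' bands.
#'
#' @param object an `lc_mediation` from [moderated_mediation()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot lc_mediation
#' @export
autoplot.lc_mediation <- function(object, ...) {
  d <- object$conditional |>
    tidyr::pivot_longer(-"w", names_to = c("effect", "bound"),
                        names_pattern = "(indirect|direct)(?:_(lo|hi))?",
                        values_to = "value") |>
    dplyr::mutate(bound = dplyr::coalesce(.data$bound, "est")) |>
    tidyr::pivot_wider(names_from = "bound", values_from = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$w)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$est)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(~effect) +
    ggplot2::labs(x = object$w, y = "conditional effect on outcome")
}

#' Plot the staircase trajectory of one participant
#'
#' Stop-signal delay over stop trials, marking successful and failed stops.
#'
#' @param trials a trial table for one participant.
#' @return a ggplot.
#' @export
plot_staircase <- function(trials) {
  d <- tibble::as_tibble(trials) |>
    dplyr::filter(.data$trial_type == "stop") |>
    dplyr::mutate(stop_trial = dplyr::row_number(),
                  outcome = ifelse(is.na(.data$response), "stopped", "responded"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stop_trial, y = .data$ssd_s)) +
    ggplot2::geom_step(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outcome), size = 1) +
    ggplot2::labs(x = "stop trial", y = "SSD (s)", colour = NULL)
}

#' Plot subregion CNR estimates against ground truth
#'
#' @param summaries tibble of `cnr_summary` rows with `true_caudal`,
#'   `true_middle`, `true_rostral` columns (as produced by the pipeline).
#' @return a ggplot.
#' @export
plot_cnr_recovery <- function(summaries) {
  d <- tibble::as_tibble(summaries) |>
    tidyr::pivot_longer(dplyr::matches("^(cnr|true)_(caudal|middle|rostral)$"),
                        names_to = c("kind", "subregion"), names_sep = "_",
                        values_to = "value") |>
    tidyr::pivot_wider(names_from = "kind", values_from = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$true, y = .data$cnr,
                                  colour = .data$subregion)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "true subregion CNR", y = "extracted mean CNR")
}
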