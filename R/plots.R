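#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot observed data and fitted curves
#'
#' Observed retention fractions with the population (typical-value) curve
#' and, optionally, each patient's empirical-Bayes curve.
#'
#' @param object A `pbms_fit`.
#' @param individual Draw per-patient empirical-Bayes curves.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pbms_fit
#' @export
autoplot.pbms_fit <- function(object, individual = FALSE, ...) {
  dat <- object$data
  grid <- seq(0, max(dat$time_h) * 1.05, length.out = 200)
  pop <- tibble::tibble(time_h = grid,
                        fraction = soef_eval(object$model_id, object$tvp,
                                             grid))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_h,
                                         y = .data$fraction)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = pop, colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "time post administration (h)",
                  y = "fraction of administered activity",
                  title = paste("Population fit,", object$model_id))
  if (individual) {
    pn <- MODEL_PARAMS[[object$model_id]]
    ebe <- empirical_bayes(object)
    eta <- as.matrix(ebe[paste0("eta_", pn)])
    ind <- purrr::map_dfr(seq_len(nrow(ebe)), function(i) {
      tibble::tibble(
        patient_id = ebe$patient_id[i], time_h = grid,
        fraction = soef_eval(object$model_id,
                             object$tvp * exp(eta[i, ]), grid))
    })
    p <- p + ggplot2::geom_line(
      data = ind,
      ggplot2::aes(group = .data$patient_id),
      alpha = 0.15, linewidth = 0.3)
  }
  p
}

#' Plot a visual predictive check
#'
#' Observed percentiles per nominal time bin against the simulated
#' percentile bands.
#'
#' @param object A `pbms_vpc`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pbms_vpc
#' @export
autoplot.pbms_vpc <- function(object, ...) {
  tab <- dplyr::mutate(object$table,
                       percentile = factor(100 * .data$prob))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$time_h,
                                    group = .data$percentile)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lo,
                                      ymax = .data$sim_hi,
                                      fill = .data$percentile),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim_mid,
                                    colour = .data$percentile),
                       linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     colour = .data$percentile)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed,
                                    colour = .data$percentile)) +
    ggplot2::labs(x = "time post administration (h)",
                  y = "fraction of administered activity",
                  title = "Visual predictive check")
}

#' Plot normalised prediction distribution errors
#'
#' NPDE against time with reference lines at 0 and +/-1.96.
#'
#' @param object A `pbms_npde`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pbms_npde
#' @export
autoplot.pbms_npde <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$time_h,
                                             y = .data$npde)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = c(-1.96, 1.96), linetype = 2) +
    ggplot2::labs(x = "time post administration (h)", y = "NPDE",
                  title = "Normalised prediction distribution errors")
}

#' Plot Akaike weights of a selection run
#'
#' @param object A `pbms_selection`.
#' @param ... Unused.
#' @return A ggplot; gated-out models are shown with zero height and
#'   marked.
#' @method autoplot pbms_selection
#' @export
autoplot.pbms_selection <- function(object, ...) {
  rep <- dplyr::mutate(object$report,
                       weight_plot = ifelse(is.na(.data$weight), 0,
                                            .data$weight),
                       gate = ifelse(.data$gate_passed, "passed",
                                     "gated out"))
  ggplot2::ggplot(rep, ggplot2::aes(x = .data$model_id,
                                    y = .data$weight_plot,
                                    fill = .data$gate)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "model", y = "Akaike weight",
                  title = "Population-based model selection")
}
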