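#' Plot a fitted race model over the observed RT distribution
#'
#' Histogram of the observed response times with the fitted defective
#' densities overlaid, error responses drawn as negative RTs so both
#' distributions share one axis.  The histogram is normalized over all
#' trials, matching the defective densities (which sum to 1 across
#' responses).
#'
#' @param object An `actrlba_fit` object.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot actrlba_fit
#' @export
autoplot.actrlba_fit <- function(object, bins = 40, ...) {
  data <- object$data
  signed <- ifelse(data$response == "correct", data$rt, -data$rt)
  grid <- race_distribution(object$lba, object$variant, n = 512)
  grid$t_signed <- ifelse(grid$response == "correct", grid$t, -grid$t)
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      ggplot2::aes(x = signed, y = ggplot2::after_stat(.data$density)),
      data = tibble::tibble(signed = signed), bins = bins,
      fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(
      ggplot2::aes(x = .data$t_signed, y = .data$density,
                   colour = .data$response),
      data = grid, linewidth = 0.8) +
    ggplot2::labs(x = "RT (s; errors negative)", y = "Density",
                  colour = "Response") +
    ggplot2::theme_minimal()
}

#' Plot a parameter-recovery study
#'
#' Three views of a [run_recovery()] result, mirroring the standard
#' panels of a recovery study report:
#' * `"scatter"` — original versus recovered values per parameter at one
#'   dataset size;
#' * `"error"` — mean absolute recovery error per parameter against
#'   dataset size;
#' * `"correlation"` — Pearson correlation between original and
#'   recovered values against dataset size.
#'
#' @param object A `recovery_result` object.
#' @param panel Which view to draw.
#' @param n_trials Dataset size for the scatter panel (default: the
#'   smallest in the study).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recovery_result
#' @export
autoplot.recovery_result <- function(object,
                                     panel = c("scatter", "error",
                                               "correlation"),
                                     n_trials = NULL, ...) {
  panel <- match.arg(panel)
  if (panel == "scatter") {
    nt <- if (is.null(n_trials)) min(object$trial_counts) else n_trials
    cells <- object$cells[object$cells$n_trials == nt &
                            object$cells$term != "sigma_c", ]
    return(
      ggplot2::ggplot(cells,
                      ggplot2::aes(x = .data$true, y = .data$estimate)) +
        ggplot2::geom_abline(linetype = 2, colour = "grey60") +
        ggplot2::geom_point(alpha = 0.7) +
        ggplot2::facet_wrap(~term, scales = "free") +
        ggplot2::labs(x = "Original value", y = "Recovered value",
                      title = paste0(nt, " trials per participant")) +
        ggplot2::theme_minimal())
  }
  s <- summarize_recovery(object)$summary
  s$is_mean <- s$term == "(mean)"
  if (panel == "error") {
    ggplot2::ggplot(s[s$term != "sigma_c", ],
                    ggplot2::aes(x = .data$n_trials,
                                 y = .data$mean_abs_error,
                                 colour = .data$term,
                                 linewidth = .data$is_mean)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::scale_linewidth_manual(values = c(0.5, 1.2),
                                      guide = "none") +
      ggplot2::labs(x = "Trials per participant",
                    y = "Mean absolute error", colour = "Parameter") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(s[!(s$term %in% c("sigma_c")), ],
                    ggplot2::aes(x = .data$n_trials, y = .data$pearson_r,
                                 colour = .data$term,
                                 linewidth = .data$is_mean)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::scale_linewidth_manual(values = c(0.5, 1.2),
                                      guide = "none") +
      ggplot2::labs(x = "Trials per participant",
                    y = "Pearson r (original vs recovered)",
                    colour = "Parameter") +
      ggplot2::theme_minimal()
  }
}
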