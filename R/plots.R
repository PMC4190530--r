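# ggplot2 display methods.

#' Plot a phase-solubility diagram with optional fitted curves
#'
#' @param data A phase-solubility tibble (`cd_total_M`, `s_total_M`).
#' @param fit Optional `complexation_fit` (or list of them) whose predicted
#'   isotherm(s) are overlaid.
#' @param free_cd_correction Evaluate overlays with the free-cyclodextrin
#'   mass-balance correction?
#' @return A ggplot object.
#' @export
plot_phase_solubility <- function(data, fit = NULL,
                                  free_cd_correction = FALSE) {
  .check_phase_data(data)
  p <- ggplot2::ggplot(data,
                       ggplot2::aes(x = .data$cd_total_M,
                                    y = .data$s_total_M)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Total cyclodextrin (mol/L)",
                  y = "Total drug solubility (mol/L)")
  if (!is.null(fit)) {
    fits <- if (inherits(fit, "complexation_fit")) list(fit) else fit
    grid <- seq(0, max(data$cd_total_M), length.out = 101)
    curves <- dplyr::bind_rows(purrr::map(fits, function(f) {
      tibble(
        cd_total_M = grid,
        s_total_M = predict_total_solubility(
          f, cd_total = grid, free_cd_correction = free_cd_correction),
        method = f$fit_method
      )
    }))
    p <- p + ggplot2::geom_line(
      data = curves,
      ggplot2::aes(colour = .data$method)
    )
  }
  p
}

#' @export
autoplot.pmf_profile <- function(object, ...) {
  has_sd <- any(is.finite(object$sd_kcal_mol))
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$lambda_A,
                                    y = .data$pmf_kcal_mol))
  if (has_sd) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$pmf_kcal_mol - .data$sd_kcal_mol,
                   ymax = .data$pmf_kcal_mol + .data$sd_kcal_mol),
      alpha = 0.25
    )
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(
      x = "Reaction coordinate (A)",
      y = "Free energy (kcal/mol)",
      title = sprintf("PMF (%s estimator)", attr(object, "estimator"))
    )
}

#' @export
autoplot.distance_series <- function(object, call = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$time_ns,
                                    y = .data$distance_A)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (ns)", y = "Centroid distance (A)")
  if (!is.null(call) && inherits(call, "state_call")) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(call),
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                   ymin = -Inf, ymax = Inf, fill = .data$state),
      alpha = 0.15, inherit.aes = FALSE
    )
  }
  p
}
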