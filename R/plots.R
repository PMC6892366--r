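#' Plot an isotopologue distribution table
#'
#' Bar chart of mass-isotopologue proportions, faceted by metabolite.
#'
#' @param distributions A tibble with columns `metabolite`, `mass_shift`,
#'   `proportion` (optionally `replicate`, averaged if present).
#' @return A ggplot object.
#' @export
plot_isotopologues <- function(distributions) {
  d <- distributions
  if ("replicate" %in% names(d)) {
    d <- dplyr::summarise(
      dplyr::group_by(d, .data$metabolite, .data$mass_shift),
      proportion = mean(.data$proportion), .groups = "drop"
    )
  }
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$mass_shift), y = .data$proportion
  )) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(~metabolite, scales = "free_x") +
    ggplot2::labs(x = "mass shift (M+k)", y = "proportion of pool") +
    ggplot2::theme_minimal()
}

#' Bifurcation plot of steady-state isotopologue proportions versus alpha
#'
#' @param object A `tca_bifurcation` tibble from [bifurcation_scan()].
#' @param ... Unused.
#' @return A ggplot object: one line per isotopologue, faceted by
#'   metabolite.
#' @method autoplot tca_bifurcation
#' @export
autoplot.tca_bifurcation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$alpha, y = .data$proportion,
    colour = factor(.data$mass_shift), group = .data$mass_shift
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metabolite) +
    ggplot2::labs(
      x = expression(alpha), y = "steady-state proportion",
      colour = "M+k"
    ) +
    ggplot2::theme_minimal()
}

#' Plot fitted against observed isotopologue distributions
#'
#' @param object A `tca_fit`.
#' @param model The `tca_model` used for the fit.
#' @param measurements The measurement table that was fitted.
#' @param ... Unused.
#' @return A ggplot object comparing the replicate-averaged observed
#'   proportions with the model prediction at the fitted alpha.
#' @method autoplot tca_fit
#' @export
autoplot.tca_fit <- function(object, model, measurements, ...) {
  obs <- normalize_measurements(measurements)
  obs <- dplyr::summarise(
    dplyr::group_by(obs, .data$metabolite, .data$mass_shift),
    proportion = mean(.data$proportion), .groups = "drop"
  )
  obs$source <- "observed"
  pred <- predict_isotopologues(model, object$alpha_mean)
  pred$source <- sprintf("predicted (alpha = %.3f)", object$alpha_mean)
  d <- dplyr::bind_rows(obs, pred)
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$mass_shift), y = .data$proportion, fill = .data$source
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metabolite, scales = "free_x") +
    ggplot2::labs(x = "mass shift (M+k)", y = "proportion", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
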