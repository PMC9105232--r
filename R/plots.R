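#' Plot a bark profile table
#'
#' One curve per stem section of the chosen quantity against stem-base
#' diameter, faceted by species -- the standard way of displaying how bark
#' properties change with tree size and position on the stem.
#'
#' @param object A `bark_profile` tibble from [bark_profile()] or
#'   [run_profile()].
#' @param quantity Column to plot: `"thickness_mm"`, `"surface_cm2"`,
#'   `"volume_cm3"`, `"mass_g"` or `"sph_g_dm2"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bark_profile
#' @export
autoplot.bark_profile <- function(object, quantity = "thickness_mm", ...) {
  if (!quantity %in% names(object)) {
    abort(sprintf("column '%s' not present (was a bark density supplied?)", quantity))
  }
  labels <- c(thickness_mm = "bark thickness (mm)",
              surface_cm2 = "bark surface (cm²)",
              volume_cm3 = "bark volume (cm³)",
              mass_g = "bark mass (g)",
              sph_g_dm2 = "specific surface mass (g dm⁻²)")
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    section = sprintf("%d–%d cm", round(.data$section_lower_cm),
                      round(.data$section_upper_cm))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$d0_mm, .data[[quantity]],
                                   colour = .data$section)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$species), scales = "free_y") +
    ggplot2::labs(x = expression(paste("stem-base diameter ", D[0], " (mm)")),
                  y = labels[[quantity]] %||% quantity,
                  colour = "stem section") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.bark_profile
#' @param data A `bark_profile` tibble.
#' @export
plot_bark_profile <- function(data, quantity = "thickness_mm") {
  autoplot.bark_profile(data, quantity = quantity)
}

#' Observed-versus-fitted plot for an allometric fit
#'
#' @param object An `"allo_fit"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot allo_fit
#' @export
autoplot.allo_fit <- function(object, ...) {
  d <- augment(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$.fitted, .data$response)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(
      x = sprintf("fitted %s", object$response_kind),
      y = sprintf("observed %s", object$response_kind),
      title = sprintf("%s (R² = %.3f)", object$model_form, object$stats$r_squared)
    ) +
    ggplot2::theme_minimal()
}
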