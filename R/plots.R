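#' Plot a FEP result
#'
#' Per-window free-energy increments with their error bars against the
#' window's starting lambda, annotated with the accumulated total.
#'
#' @param object A `fep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fep_result
#' @export
autoplot.fep_result <- function(object, ...) {
  w <- tidy(object)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$lambda_from, y = .data$dg)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$dg - .data$eps,
                                          ymax = .data$dg + .data$eps)) +
    ggplot2::geom_line(linetype = "dotted") +
    ggplot2::labs(
      x = expression(lambda[i]),
      y = expression(Delta * G[i * "," * i + 1] ~ "(kJ/mol)"),
      title = sprintf("Accumulated singlet-triplet ΔG = %.2f ± %.2f kJ/mol",
                      object$total_dg, object$total_eps)) +
    ggplot2::theme_minimal()
}

#' Plot an energy series
#'
#' Traces of the singlet, triplet and mixed energies along the sampled
#' window; the vertical spread of `e_triplet - e_singlet` is what the FEP
#' estimator consumes.
#'
#' @param object An [energy_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot energy_series
#' @export
autoplot.energy_series <- function(object, ...) {
  long <- tibble(
    step = rep(object$step, 3),
    energy = c(object$e_singlet, object$e_triplet, object$e_mix),
    state = rep(c("singlet", "triplet", "mixed"), each = nrow(object)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$energy,
                                     colour = .data$state)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "step", y = "energy (kJ/mol)",
                  title = sprintf("Window λ = %g, T = %g K",
                                  series_lambda(object),
                                  series_temperature(object))) +
    ggplot2::theme_minimal()
}

#' Plot fragment spin populations
#'
#' Bar chart of per-fragment spin sums with the localization threshold line;
#' the visual analogue of a localized-vs-delocalized triplet comparison.
#'
#' @param object A `spin_localization` from [classify_localization()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spin_localization
#' @export
autoplot.spin_localization <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fragment, y = .data$spin)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$threshold * object$total_spin,
                        linetype = "dashed") +
    ggplot2::labs(x = "fragment", y = "Mulliken spin population",
                  title = sprintf("%s triplet (index %.2f)",
                                  object$label, object$localization_index)) +
    ggplot2::theme_minimal()
}
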