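#' Tidy a FEP result into its per-window table
#'
#' @param x A `fep_result` from [fep_estimate()] or [accumulate_windows()].
#' @param ... Unused.
#' @return A tibble with one row per lambda window: `lambda_from`,
#'   `lambda_to`, `dg`, `eps`, `r1`, `sampling_ratio`, `n`.
#' @method tidy fep_result
#' @export
tidy.fep_result <- function(x, ...) {
  as_tibble(x$windows)
}

#' One-row summary of a FEP result
#'
#' @inheritParams tidy.fep_result
#' @return A one-row tibble with `total_dg`, `total_eps`, `n_windows`,
#'   `n_samples`, `temperature`.
#' @method glance fep_result
#' @export
glance.fep_result <- function(x, ...) {
  tibble(total_dg = x$total_dg, total_eps = x$total_eps,
         n_windows = nrow(x$windows),
         n_samples = if ("n" %in% names(x$windows))
           sum(x$windows$n) else NA_integer_,
         temperature = x$temperature)
}

#' Tidy an endpoint Delta-U result
#'
#' @param x A `delta_u_result` from [delta_u()].
#' @param ... Unused.
#' @return A one-row tibble with `du`, `sd`, `n_singlet`, `n_triplet`.
#' @method tidy delta_u_result
#' @export
tidy.delta_u_result <- function(x, ...) {
  tibble(du = x$du, sd = x$sd, n_singlet = x$n_singlet,
         n_triplet = x$n_triplet)
}

#' Tidy a spin-localization result
#'
#' @param x A `spin_localization` from [classify_localization()].
#' @param ... Unused.
#' @return The fragment-sum tibble with the per-fragment spin share.
#' @method tidy spin_localization
#' @export
tidy.spin_localization <- function(x, ...) {
  dplyr::mutate(as_tibble(x$fragment_sums),
                share = .data$spin / x$total_spin)
}

#' @rdname tidy.spin_localization
#' @method glance spin_localization
#' @export
glance.spin_localization <- function(x, ...) {
  tibble(label = x$label, localization_index = x$localization_index,
         dominant_fragment = x$dominant_fragment, threshold = x$threshold,
         total_spin = x$total_spin)
}
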