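#' Per-window perturbation record
#'
#' A `window_record` holds the ordered samples of the energy gap
#' \eqn{\Delta H = H_j - H_i} evaluated on configurations drawn from window
#' \eqn{i}, together with the two lambda values and the sampling temperature.
#' This is the raw input of the Zwanzig estimator.
#'
#' For an affine lambda mixture the gap between two windows reduces to
#' \eqn{\Delta H = (\lambda_j - \lambda_i)(E_T - E_S)} frame by frame, which
#' is how [window_record_from_series()] builds records from an
#' [energy_series()] without re-evaluating any backend.
#'
#' @param dh Numeric vector of energy-gap samples (kJ/mol), ordered as
#'   sampled.
#' @param lambda_from,lambda_to Lambda of the sampled ensemble and of the
#'   perturbed-to state; must differ.
#' @param temperature Sampling temperature in K.
#' @return A list of class `window_record`.
#' @export
window_record <- function(dh, lambda_from, lambda_to, temperature) {
  dh <- as.numeric(dh)
  if (length(dh) == 0) abort("`dh` must be non-empty.")
  if (any(!is.finite(dh))) abort("`dh` contains non-finite samples.")
  if (!is.finite(lambda_from) || !is.finite(lambda_to) ||
      lambda_from == lambda_to) {
    abort("`lambda_from` and `lambda_to` must be distinct finite values.")
  }
  stopifnot(temperature > 0)
  structure(list(dh = dh, lambda_from = lambda_from, lambda_to = lambda_to,
                 temperature = temperature),
            class = "window_record")
}

#' @rdname window_record
#' @param series An [energy_series()] sampled at `lambda_from`.
#' @export
window_record_from_series <- function(series, lambda_to) {
  stopifnot(inherits(series, "energy_series"))
  lam_i <- series_lambda(series)
  window_record((lambda_to - lam_i) * (series$e_triplet - series$e_singlet),
                lambda_from = lam_i, lambda_to = lambda_to,
                temperature = series_temperature(series))
}

#' Zwanzig free-energy estimate for one window
#'
#' The exponential-averaging (free energy perturbation) estimator
#' \deqn{\Delta G_{i \to j} = -k_B T \,
#'   \ln \langle e^{-\Delta H / k_B T} \rangle_i}
#' computed in log-sum-exp form (shifted by the extreme exponent) so that the
#' average neither overflows nor underflows even for \eqn{|\Delta H|} of order
#' 1e4 kJ/mol. A constant series is handled exactly: \eqn{\Delta H \equiv c}
#' gives \eqn{\Delta G = c} with no rounding through the exponential.
#'
#' @param record A [window_record()].
#' @return The window free-energy difference in kJ/mol.
#' @export
zwanzig_dg <- function(record) {
  stopifnot(inherits(record, "window_record"))
  kbt <- kT(record$temperature)
  y <- -record$dh / kbt
  m <- max(y)
  # -kBT * (log mean exp(y)); exp(y - m) <= 1 so the sum is safe
  -kbt * (m + log(mean(exp(y - m))))
}

#' Lag-1 autocorrelation of an ordered series
#'
#' \deqn{r_1 = \frac{\sum_{i \ge 2} (x_i - \bar x)(x_{i-1} - \bar x)}
#'                  {\sum_i (x_i - \bar x)^2}}
#' A zero-variance (constant) series carries no correlation information and
#' returns 0 by convention. Inside the error model the series is the vector
#' of per-sample Boltzmann factors; this function itself accepts any ordered
#' numeric series.
#'
#' @param x Ordered numeric series, length >= 3.
#' @return The lag-1 autocorrelation coefficient.
#' @seealso [sampling_ratio()]
#' @export
lag1_autocorrelation <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) abort("Need at least 3 samples for a lag-1 autocorrelation.")
  d <- x - mean(x)
  denom <- sum(d^2)
  if (denom == 0) return(0)
  sum(d[-1] * d[-n]) / denom
}

# clamp r1 strictly inside (-1, 1) before forming the sampling ratio
clamp_r1 <- function(r1, eps = 1e-12) min(max(r1, -1 + eps), 1 - eps)

#' Sampling ratio from the lag-1 autocorrelation
#'
#' The serial-correlation inflation factor of the variance of an ensemble
#' average, \eqn{1 + 2\tau = (1 + r_1) / (1 - r_1)}, where \eqn{\tau} is the
#' correlation length. Independent samples (\eqn{r_1 = 0}) give 1;
#' anticorrelated samples give a ratio below 1.
#'
#' @param r1 Lag-1 autocorrelation, strictly inside (-1, 1).
#' @return The sampling ratio \eqn{1 + 2\tau}.
#' @export
sampling_ratio <- function(r1) {
  if (!is.finite(r1) || abs(r1) >= 1) {
    abort("`r1` must lie strictly inside (-1, 1); clamp upstream.")
  }
  (1 + r1) / (1 - r1)
}

#' First-order (Chipot) error of a window free energy
#'
#' First-order error propagation for the Zwanzig estimate. With
#' \eqn{X_i = e^{-\Delta H_i / k_B T}}, the statistical error of the ensemble
#' average is
#' \deqn{\delta\varepsilon^2 = \frac{1 + 2\tau}{N}
#'   \left(\langle X^2 \rangle - \langle X \rangle^2\right)}
#' with the sampling ratio \eqn{1 + 2\tau = (1+r_1)/(1-r_1)} computed from the
#' lag-1 autocorrelation of the \eqn{X_i} themselves, and the free-energy
#' error follows by propagating through \eqn{-k_B T \ln m}:
#' \deqn{\varepsilon = k_B T \, \delta\varepsilon / \langle X \rangle.}
#' All arithmetic is done on max-shifted exponentials, so the result is exact
#' under a constant shift of \eqn{\Delta H} and safe for large gaps.
#'
#' Two published-form toggles are kept for comparison: `variance_form =
#' "printed"` uses \eqn{\langle X \rangle - \langle X \rangle^2} literally in
#' place of the sample variance, and `mean_position = "multiply"` multiplies
#' by \eqn{\langle X \rangle} instead of dividing. The defaults are the
#' standard delta-method forms.
#'
#' @param record A [window_record()] with at least 2 samples.
#' @param variance_form `"sample"` (default) or `"printed"`.
#' @param mean_position `"divide"` (default) or `"multiply"`.
#' @return A list with `eps` (kJ/mol), `r1`, `sampling_ratio` and `n`.
#' @export
chipot_error <- function(record, variance_form = c("sample", "printed"),
                         mean_position = c("divide", "multiply")) {
  stopifnot(inherits(record, "window_record"))
  variance_form <- match.arg(variance_form)
  mean_position <- match.arg(mean_position)
  n <- length(record$dh)
  if (n < 2) abort("Need at least 2 samples for an error estimate.")
  kbt <- kT(record$temperature)
  y <- -record$dh / kbt
  m <- max(y)
  u <- exp(y - m)          # X_i = e^m * u_i with u_i in (0, 1]
  u_bar <- mean(u)
  r1 <- if (n >= 3) clamp_r1(lag1_autocorrelation(u)) else 0
  ratio <- sampling_ratio(r1)
  if (variance_form == "sample") {
    var_u <- max(mean(u^2) - u_bar^2, 0)
    delta_eps_rel <- sqrt(ratio / n * var_u)   # = delta_eps / e^m
    eps <- switch(mean_position,
      divide = kbt * delta_eps_rel / u_bar,
      multiply = kbt * delta_eps_rel * u_bar * exp(2 * m))
  } else {
    # literal printed form <X> - <X>^2 on the unshifted scale; comparison
    # toggle only, so no overflow protection beyond finite checks
    x_bar <- exp(m) * u_bar
    delta_eps <- sqrt(max(ratio / n * (x_bar - x_bar^2), 0))
    eps <- switch(mean_position,
      divide = kbt * delta_eps / x_bar,
      multiply = kbt * delta_eps * x_bar)
  }
  list(eps = eps, r1 = r1, sampling_ratio = ratio, n = n)
}

#' Estimate one window: free energy plus error diagnostics
#'
#' Runs [zwanzig_dg()] and [chipot_error()] on one [window_record()] and
#' returns a one-row tibble -- the unit that [accumulate_windows()] sums.
#'
#' @inheritParams chipot_error
#' @param ... Error-model toggles passed to [chipot_error()].
#' @return A one-row tibble with columns `lambda_from`, `lambda_to`, `dg`,
#'   `eps`, `r1`, `sampling_ratio`, `n`.
#' @export
estimate_window <- function(record, ...) {
  stopifnot(inherits(record, "window_record"))
  err <- if (length(record$dh) >= 2) {
    chipot_error(record, ...)
  } else {
    list(eps = NA_real_, r1 = NA_real_, sampling_ratio = NA_real_, n = 1L)
  }
  tibble(lambda_from = record$lambda_from, lambda_to = record$lambda_to,
         dg = zwanzig_dg(record), eps = err$eps, r1 = err$r1,
         sampling_ratio = err$sampling_ratio, n = as.integer(err$n))
}

#' Accumulate per-window estimates into a total free energy
#'
#' Sums the per-window free energies over a contiguous lambda schedule:
#' \eqn{\Delta G = \sum_i \Delta G_{i, i+1}}. Windows are sampled from
#' independent trajectories, so the total error is the quadrature sum
#' \eqn{\varepsilon_{tot} = \sqrt{\sum_i \varepsilon_i^2}}. The windows must
#' tile \[0, 1\] exactly: each window's `lambda_to` equals the next window's
#' `lambda_from`, starting at 0 and ending at 1; gaps or overlaps raise a
#' schedule error.
#'
#' @param windows A tibble of window estimates as produced by
#'   [estimate_window()] (rows in schedule order or any order; they are
#'   sorted by `lambda_from`).
#' @param temperature Temperature in K recorded on the result (informational).
#' @return A `fep_result` object; see [tidy()] and [glance()] methods.
#' @export
accumulate_windows <- function(windows, temperature = NA_real_) {
  windows <- as_tibble(windows)
  req <- c("lambda_from", "lambda_to", "dg", "eps")
  if (!all(req %in% names(windows))) {
    abort(paste0("`windows` must have columns: ", paste(req, collapse = ", ")))
  }
  windows <- dplyr::arrange(windows, .data$lambda_from)
  lam <- c(windows$lambda_from, windows$lambda_to[nrow(windows)])
  if (abs(lam[1]) > 0 || abs(lam[length(lam)] - 1) > 0 ||
      any(windows$lambda_to[-nrow(windows)] != windows$lambda_from[-1]) ||
      any(diff(lam) <= 0)) {
    abort(paste0(
      "Window schedule must tile [0, 1] contiguously and increasingly; got ",
      paste(sprintf("%g->%g", windows$lambda_from, windows$lambda_to),
            collapse = ", ")), class = "spinfep_schedule_error")
  }
  structure(
    list(windows = windows,
         total_dg = sum(windows$dg),
         total_eps = sqrt(sum(windows$eps^2)),
         lambda_schedule = lam,
         temperature = temperature),
    class = "fep_result")
}

#' @export
print.fep_result <- function(x, ...) {
  cat("<fep_result>\n")
  cat(sprintf("  schedule: {%s}\n", paste(x$lambda_schedule, collapse = ", ")))
  cat(sprintf("  total dG = %.4f +/- %.4f kJ/mol (%d windows)\n",
              x$total_dg, x$total_eps, nrow(x$windows)))
  invisible(x)
}

#' Full FEP estimate from per-window energy series
#'
#' The forward estimation pipeline: given one [energy_series()] per lambda of
#' a strictly increasing schedule from 0 to 1, builds the forward perturbation
#' record of each adjacent pair (ensemble of window \eqn{i} perturbed to
#' \eqn{i+1}), estimates each window with [estimate_window()], and accumulates
#' the totals. All series must share one temperature; mixed temperatures are
#' refused rather than silently reweighted.
#'
#' @param series_list List of [energy_series()], one per lambda (any order).
#' @param ... Passed on to [chipot_error()] (error-model toggles).
#' @return A `fep_result`.
#' @export
fep_estimate <- function(series_list, ...) {
  stopifnot(is.list(series_list), length(series_list) >= 2)
  lams <- vapply(series_list, series_lambda, numeric(1))
  series_list <- series_list[order(lams)]
  lams <- sort(lams)
  if (anyDuplicated(lams)) abort("Duplicate lambda values in series list.")
  temps <- vapply(series_list, series_temperature, numeric(1))
  if (diff(range(temps)) > 1e-9) {
    abort("All series must share one temperature; cross-temperature estimation is refused.")
  }
  windows <- purrr::map2_dfr(
    series_list[-length(series_list)], lams[-1],
    function(s, lam_next) {
      estimate_window(window_record_from_series(s, lam_next), ...)
    })
  accumulate_windows(windows, temperature = temps[1])
}

#' Endpoint internal-energy difference (the Delta-U baseline)
#'
#' The conventional estimate that FEP is designed to outperform: the
#' difference of mean energies between two independently sampled endpoint
#' ensembles,
#' \deqn{\Delta U = \overline{E_T}\big|_{\lambda=1} -
#'                 \overline{E_S}\big|_{\lambda=0},}
#' each state's own Hamiltonian averaged over its own ensemble (the `e_mix`
#' column of each endpoint series). The quoted error is the standard
#' deviation of the raw per-frame data (not of the mean), combined across the
#' two ensembles as \eqn{\sqrt{SD_S^2 + SD_T^2}}; it therefore carries the
#' full environment-energy fluctuation, which is exactly what cancels inside
#' the FEP gap.
#'
#' @param series_singlet An [energy_series()] at lambda = 0.
#' @param series_triplet An [energy_series()] at lambda = 1.
#' @return A list of class `delta_u_result` with `du`, `sd`, `n_singlet`,
#'   `n_triplet`.
#' @export
delta_u <- function(series_singlet, series_triplet) {
  stopifnot(inherits(series_singlet, "energy_series"),
            inherits(series_triplet, "energy_series"))
  if (series_lambda(series_singlet) != 0 ||
      series_lambda(series_triplet) != 1) {
    abort("delta_u requires endpoint series labelled lambda = 0 and lambda = 1.")
  }
  es <- series_singlet$e_mix
  et <- series_triplet$e_mix
  sd_s <- if (length(es) > 1) sd(es) else 0
  sd_t <- if (length(et) > 1) sd(et) else 0
  structure(list(du = mean(et) - mean(es), sd = sqrt(sd_s^2 + sd_t^2),
                 n_singlet = length(es), n_triplet = length(et)),
            class = "delta_u_result")
}

#' @export
print.delta_u_result <- function(x, ...) {
  cat(sprintf("<delta_u_result> dU = %.2f +/- %.2f kJ/mol (n = %d + %d)\n",
              x$du, x$sd, x$n_singlet, x$n_triplet))
  invisible(x)
}

#' Forward/backward overlap diagnostic for one window pair
#'
#' Convergence diagnostic for adjacent windows: the forward gap distribution
#' (\eqn{H_j - H_i} on the ensemble of \eqn{i}) and the mirrored backward one
#' (\eqn{-(H_i - H_j)} on the ensemble of \eqn{j}) must overlap for
#' exponential averaging to converge. Reports the histogram-intersection
#' overlap of the two distributions (1 = identical, 0 = disjoint) and the
#' forward/backward closure discrepancy \eqn{\Delta G_{fwd} + \Delta G_{bwd}},
#' which is zero in the converged limit.
#'
#' @param forward [window_record()] of the forward perturbation (i to j).
#' @param backward [window_record()] of the backward perturbation (j to i).
#' @param n_bins Number of histogram bins over the pooled range.
#' @return A list with `overlap`, `discrepancy`, `dg_forward`, `dg_backward`.
#' @export
window_overlap <- function(forward, backward, n_bins = 50) {
  stopifnot(inherits(forward, "window_record"),
            inherits(backward, "window_record"))
  fwd <- forward$dh
  bwd <- -backward$dh     # mirror so both live on the forward-gap axis
  rng <- range(fwd, bwd)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h_f <- tabulate(findInterval(fwd, breaks, rightmost.closed = TRUE),
                  nbins = n_bins) / length(fwd)
  h_b <- tabulate(findInterval(bwd, breaks, rightmost.closed = TRUE),
                  nbins = n_bins) / length(bwd)
  list(overlap = sum(pmin(h_f, h_b)),
       discrepancy = zwanzig_dg(forward) + zwanzig_dg(backward),
       dg_forward = zwanzig_dg(forward),
       dg_backward = zwanzig_dg(backward))
}
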