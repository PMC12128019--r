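#' Harmonic two-state test system with its exact free energy
#'
#' Builds a `harmonic_pair` [two_state_system()] with a prescribed triplet
#' energy offset and per-coordinate force-constant ratio, and returns it
#' together with its closed-form free-energy difference at `temperature` --
#' the oracle every estimator test compares against. With a `seed` the state
#' minima receive small random displacements (so the two surfaces are not
#' trivially concentric) while the oracle value is unaffected: for harmonic
#' wells \eqn{\Delta F} depends only on the offsets and force-constant
#' ratios.
#'
#' @param delta_e0 Triplet minus singlet energy offset, kJ/mol.
#' @param k_ratio Per-coordinate triplet/singlet force-constant ratio
#'   (recycled to `n_coords`).
#' @param n_coords Number of coordinates (1D particles).
#' @param k_base Singlet force constants, kJ/mol/A^2 (recycled).
#' @param temperature Temperature in K for the oracle value.
#' @param seed Optional seed for randomized minima displacements.
#' @return A list with `system` and `delta_f` (kJ/mol).
#' @export
make_harmonic_pair <- function(delta_e0 = 10, k_ratio = 1, n_coords = 1,
                               k_base = 1, temperature = 300, seed = NULL) {
  stopifnot(n_coords >= 1, all(k_ratio > 0), all(k_base > 0))
  k_s <- rep_len(k_base, n_coords)
  k_t <- k_s * rep_len(k_ratio, n_coords)
  x0_s <- numeric(n_coords)
  x0_t <- numeric(n_coords)
  if (!is.null(seed)) {
    withr::local_seed(as.integer(seed))
    x0_s <- rnorm(n_coords, 0, 0.3)
    x0_t <- x0_s + rnorm(n_coords, 0, 0.3)
  }
  sys <- two_state_system("harmonic_pair", params = list(
    k_s = k_s, k_t = k_t, x0_s = x0_s, x0_t = x0_t,
    e0_s = 0, e0_t = delta_e0))
  list(system = sys, delta_f = analytic_delta_f(sys, temperature))
}

#' Two-state system with a large common-mode environment term
#'
#' Synthetic analogue of a QM/MM setting: a harmonic solute pair whose
#' singlet-triplet gap carries the signal, plus a bath of harmonic
#' environment modes whose potential energy enters both electronic states
#' identically. The bath energy fluctuates strongly -- for `n` modes at
#' temperature `T` the instantaneous potential-energy SD is
#' \eqn{\sqrt{n/2}\, k_B T} (chi-squared fluctuations) -- so the endpoint
#' \eqn{\Delta U} error inherits it in full, while it cancels exactly inside
#' the per-frame gap \eqn{E_T - E_S} used by FEP. The mode count is chosen so
#' the realized SD matches `target_env_sd` within 5\%; an unreachable target
#' (below one mode's SD, or needing more than 1e5 modes) is a parameter
#' error.
#'
#' The default target of 40 kJ/mol at 300 K needs about 514 modes and sits in
#' the tens-of-kJ/mol regime typical of reported endpoint-average errors in
#' QM/MM spin-state calculations; the default solute carries a 300 kJ/mol
#' singlet-triplet offset, the scale of thymine triplet energies.
#'
#' @param target_env_sd Desired SD of the instantaneous environment potential
#'   energy, kJ/mol.
#' @param temperature Temperature in K at which the SD is realized.
#' @param solute Optional harmonic solute parameter list (as the `params` of
#'   a `harmonic_pair` backend); default: 2 coordinates, `delta_e0 = 300`,
#'   `k_ratio = 1.2`.
#' @param env_k Environment mode force constant, kJ/mol/A^2 (does not affect
#'   the energy SD; sets length scales only).
#' @param max_modes Mode-count cap before the target is declared unreachable.
#' @return A [two_state_system()] with a `noisy_environment` backend.
#' @export
make_noisy_environment <- function(target_env_sd = 40, temperature = 300,
                                   solute = NULL, env_k = 100,
                                   max_modes = 1e5) {
  stopifnot(target_env_sd > 0, temperature > 0)
  if (is.null(solute)) {
    solute <- list(k_s = c(1, 1), k_t = c(1.2, 1.2),
                   x0_s = c(0, 0), x0_t = c(0.2, -0.2),
                   e0_s = 0, e0_t = 300)
  }
  kbt <- kT(temperature)
  # SD of n harmonic-mode potential energies at T: sqrt(n/2) * kBT
  n_env <- max(1L, as.integer(round(2 * (target_env_sd / kbt)^2)))
  if (n_env > max_modes) {
    abort(sprintf(
      "target_env_sd = %g needs %d environment modes (> %g allowed).",
      target_env_sd, n_env, max_modes), class = "spinfep_parameter_error")
  }
  realized <- sqrt(n_env / 2) * kbt
  if (abs(realized - target_env_sd) / target_env_sd > 0.05) {
    abort(sprintf(
      "target_env_sd = %g unreachable: nearest mode count %d realizes SD %.3g (error > 5%%).",
      target_env_sd, n_env, realized), class = "spinfep_parameter_error")
  }
  two_state_system("noisy_environment",
                   params = list(solute = solute, n_env = n_env,
                                 env_k = env_k))
}

#' Stationary AR(1) series with known lag-1 autocorrelation
#'
#' Draws a stationary first-order autoregressive series
#' \eqn{x_i = \rho x_{i-1} + \sqrt{1-\rho^2}\, \eta_i} scaled to marginal
#' mean `mean` and SD `sd`; its population lag-1 autocorrelation is exactly
#' `rho`. Calibration input for the sampling-ratio correction.
#'
#' @param rho Lag-1 autocorrelation, |rho| < 1.
#' @param n Series length.
#' @param seed Integer seed.
#' @param mean,sd Marginal mean and standard deviation.
#' @return Numeric vector of length `n`.
#' @export
generate_ar1 <- function(rho, n, seed = 1L, mean = 0, sd = 1) {
  if (!is.finite(rho) || abs(rho) >= 1) abort("`rho` must satisfy |rho| < 1.")
  stopifnot(n >= 1, sd >= 0)
  withr::local_seed(as.integer(seed))
  z <- numeric(n)
  z[1] <- rnorm(1)
  if (n > 1) {
    eta <- rnorm(n - 1) * sqrt(1 - rho^2)
    for (i in 2:n) z[i] <- rho * z[i - 1] + eta[i - 1]
  }
  mean + sd * z
}

#' IID Gaussian energy-gap series as a window record
#'
#' Draws \eqn{\Delta H_i \sim N(\mu, \sigma^2)} and wraps them as a single
#' 0 to 1 [window_record()]. For this input the Zwanzig estimate converges
#' to the lognormal closed form \eqn{\mu - \sigma^2 / (2 k_B T)}, which makes
#' it the canonical estimator-calibration fixture.
#'
#' @param mu Mean gap, kJ/mol.
#' @param sigma Gap SD, kJ/mol (0 gives a constant series).
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param temperature Temperature in K.
#' @return A [window_record()] spanning lambda 0 to 1.
#' @export
generate_gaussian_dh <- function(mu, sigma, n, seed = 1L, temperature = 300) {
  stopifnot(sigma >= 0, n >= 1)
  withr::local_seed(as.integer(seed))
  window_record(rnorm(n, mu, sigma), lambda_from = 0, lambda_to = 1,
                temperature = temperature)
}

#' Theoretical Zwanzig limit for a Gaussian gap distribution
#'
#' For \eqn{\Delta H \sim N(\mu, \sigma^2)} the exponential average is the
#' lognormal moment \eqn{e^{-\mu/k_BT + \sigma^2/(2 k_B^2 T^2)}}, so
#' \eqn{\Delta G = \mu - \sigma^2 / (2 k_B T)} exactly.
#'
#' @inheritParams generate_gaussian_dh
#' @return The limiting free energy, kJ/mol.
#' @export
gaussian_dg_limit <- function(mu, sigma, temperature = 300) {
  mu - sigma^2 / (2 * kT(temperature))
}
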