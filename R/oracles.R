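#' Closed-form free-energy difference of a harmonic two-state system
#'
#' For two sets of independent classical harmonic wells, the configurational
#' free-energy difference between the triplet and singlet states is
#' \deqn{\Delta F = (E_{0,T} - E_{0,S}) +
#'   \frac{k_B T}{2} \sum_i \ln\frac{k_{T,i}}{k_{S,i}}}
#' (Gaussian configuration integrals; the kinetic contribution is
#' state-independent and cancels). A `noisy_environment` backend is accepted
#' too: its common-mode environment term cancels exactly, so its \eqn{\Delta F}
#' equals that of its harmonic solute.
#'
#' @param system A [two_state_system()] with a `harmonic_pair` or
#'   `noisy_environment` backend.
#' @param temperature Temperature in K.
#' @return \eqn{\Delta F} (triplet minus singlet) in kJ/mol.
#' @seealso [quadrature_delta_f()] for the brute-force partition-function
#'   oracle this agrees with.
#' @export
analytic_delta_f <- function(system, temperature) {
  stopifnot(temperature > 0)
  p <- switch(system$backend,
    harmonic_pair = system$params,
    noisy_environment = system$params$solute,
    abort(sprintf(
      "analytic_delta_f requires a harmonic backend, got '%s'.",
      system$backend), class = "spinfep_unsupported_backend"))
  (p$e0_t - p$e0_s) + 0.5 * kT(temperature) * sum(log(p$k_t / p$k_s))
}

#' Free-energy difference by direct partition-function quadrature
#'
#' Brute-force oracle: numerically integrates the Boltzmann weights
#' \eqn{e^{-E(x)/k_B T}} of both states on a regular grid and returns
#' \eqn{\Delta F = -k_B T \ln(Z_T / Z_S)}. Restricted to systems with at most
#' two coordinates (a full tensor grid). The grid is sized automatically to
#' cover at least `half_width_sd` thermal standard deviations of both states'
#' wells; if the integrand has not decayed at the grid boundary the result
#' would be truncated, so an accuracy error is raised instead.
#'
#' @inheritParams analytic_delta_f
#' @param system A [two_state_system()] with at most 2 coordinates (any
#'   evaluable backend).
#' @param n_grid Grid points per coordinate.
#' @param half_width_sd Half-width of the grid in thermal standard deviations
#'   (must be >= 8).
#' @param boundary_tol Maximum allowed ratio of the boundary Boltzmann weight
#'   to the grid maximum.
#' @return \eqn{\Delta F} in kJ/mol.
#' @export
quadrature_delta_f <- function(system, temperature, n_grid = 4001,
                               half_width_sd = 10, boundary_tol = 1e-10) {
  stopifnot(temperature > 0)
  if (half_width_sd < 8) abort("`half_width_sd` must be >= 8.")
  nc <- n_coords(system)
  if (nc > 2) abort("quadrature_delta_f supports at most 2 coordinates.")
  beta <- 1 / kT(temperature)

  # thermal width per coordinate estimated from the local curvature at each
  # state's minimum; quartic wells get a conservative width from a4 as well
  lims <- quadrature_limits(system, temperature, half_width_sd)
  grids <- lapply(seq_len(nc), function(i) {
    seq(lims$lo[i], lims$hi[i], length.out = n_grid)
  })

  log_z <- function(state) {
    if (nc == 1) {
      e <- vapply(grids[[1]],
                  function(x) backend_energy(system, x, state)$energy,
                  numeric(1))
      le <- -beta * e
      m <- max(le)
      list(log_z = m + log(sum(exp(le - m))) +
             log(diff(grids[[1]][1:2])),
           boundary = max(exp(le[1] - m), exp(le[n_grid] - m)))
    } else {
      le <- outer(grids[[1]], grids[[2]], Vectorize(function(a, b) {
        -beta * backend_energy(system, c(a, b), state)$energy
      }))
      m <- max(le)
      w <- exp(le - m)
      edge <- max(w[1, ], w[n_grid, ], w[, 1], w[, n_grid])
      list(log_z = m + log(sum(w)) + log(diff(grids[[1]][1:2])) +
             log(diff(grids[[2]][1:2])),
           boundary = edge)
    }
  }
  zs <- log_z("singlet")
  zt <- log_z("triplet")
  if (max(zs$boundary, zt$boundary) > boundary_tol) {
    abort(paste0(
      "Quadrature grid too narrow: Boltzmann weight at the boundary is ",
      sprintf("%.2e", max(zs$boundary, zt$boundary)),
      " of the maximum; widen `half_width_sd`."),
      class = "spinfep_accuracy_error")
  }
  -kT(temperature) * (zt$log_z - zs$log_z)
}

# grid bounds covering both states' wells out to half_width_sd thermal SDs
quadrature_limits <- function(system, temperature, half_width_sd) {
  nc <- n_coords(system)
  kbt <- kT(temperature)
  lo <- numeric(nc); hi <- numeric(nc)
  p <- system$params
  per_state <- function(state) {
    if (system$backend == "harmonic_pair") {
      k <- if (state == "singlet") p$k_s else p$k_t
      x0 <- if (state == "singlet") p$x0_s else p$x0_t
      sdv <- sqrt(kbt / k)
    } else if (system$backend == "quartic_pair") {
      a4 <- if (state == "singlet") p$a4_s else p$a4_t
      a2 <- if (state == "singlet") p$a2_s else p$a2_t
      x0 <- if (state == "singlet") p$x0_s else p$x0_t
      # width of the wider of the quadratic and quartic envelopes
      sd_q <- ifelse(a2 > 0, sqrt(kbt / (2 * a2)), Inf)
      sd_4 <- ifelse(a4 > 0, (kbt / a4)^0.25, Inf)
      sdv <- pmin(sd_q, sd_4)
      if (any(!is.finite(sdv))) abort("Unbound quartic well.")
    } else if (system$backend == "noisy_environment") {
      ns <- length(p$solute$k_s)
      k <- c(if (state == "singlet") p$solute$k_s else p$solute$k_t,
             rep(p$env_k, p$n_env))
      x0 <- c(if (state == "singlet") p$solute$x0_s else p$solute$x0_t,
              rep(0, p$n_env))
      sdv <- sqrt(kbt / k)
    } else {
      abort("Unsupported backend for quadrature.",
            class = "spinfep_unsupported_backend")
    }
    list(lo = x0 - half_width_sd * sdv, hi = x0 + half_width_sd * sdv)
  }
  s <- per_state("singlet"); t <- per_state("triplet")
  list(lo = pmin(s$lo, t$lo), hi = pmax(s$hi, t$hi))
}
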