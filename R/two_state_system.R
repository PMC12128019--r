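#' Define a two-electronic-state system
#'
#' A `two_state_system` bundles the particle layout (count, spatial dimension,
#' masses, frozen mask) with a backend that supplies the potential energy and
#' gradient of two electronic states -- conventionally the singlet ground state
#' and the triplet excited state -- at any nuclear configuration. The
#' lambda-mixed alchemical Hamiltonian \eqn{H(\lambda) = (1-\lambda) H_S +
#' \lambda H_T} interpolates between them.
#'
#' Available backends:
#' \describe{
#'   \item{`harmonic_pair`}{Independent per-coordinate harmonic wells for each
#'     state: force constants `k_s`, `k_t` (kJ/mol/A^2), minima `x0_s`, `x0_t`
#'     (A), energy offsets `e0_s`, `e0_t` (kJ/mol). Admits a closed-form free
#'     energy difference, so it is the main validation backend.}
#'   \item{`quartic_pair`}{Per-coordinate quartic-plus-quadratic wells
#'     \eqn{a_4 (x-x_0)^4 + a_2 (x-x_0)^2 + E_0} per state; anharmonic test
#'     surface with analytic gradients.}
#'   \item{`noisy_environment`}{A harmonic solute pair plus `n_env` harmonic
#'     environment modes (force constant `env_k`, minima at 0) whose energy is
#'     added *identically* to both states. The common-mode term emulates the
#'     large molecular-mechanics environment fluctuations of a QM/MM setting:
#'     it dominates the raw energy variance but cancels exactly inside the
#'     singlet-triplet gap. See [make_noisy_environment()].}
#'   \item{`external_stub`}{Documents the adapter contract a real quantum
#'     chemistry engine must satisfy (energy plus gradient for both spin states
#'     per call); raises on evaluation.}
#' }
#'
#' @param backend Backend name, one of `"harmonic_pair"`, `"quartic_pair"`,
#'   `"noisy_environment"`, `"external_stub"`.
#' @param params Named list of backend parameters (see Details).
#' @param n_particles Positive integer particle count.
#' @param dim Spatial dimension per particle (1, 2 or 3). Total coordinate
#'   count is `n_particles * dim`.
#' @param masses Per-particle masses in amu, recycled if length one.
#' @param frozen Logical per-particle frozen mask; frozen particles never move
#'   during dynamics (their gradients are still reported by the backend).
#'
#' @return An object of class `two_state_system`.
#' @seealso [state_energy()], [mixed_energy()], [analytic_delta_f()]
#' @export
#' @examples
#' sys <- two_state_system("harmonic_pair",
#'   params = list(k_s = 1, k_t = 2, x0_s = 0, x0_t = 0, e0_s = 0, e0_t = 10))
#' state_energy(sys, x = 2, state = "singlet")
two_state_system <- function(backend, params = list(), n_particles = NULL,
                             dim = 1, masses = 1,
                             frozen = FALSE) {
  backend <- match.arg(backend, c("harmonic_pair", "quartic_pair",
                                  "noisy_environment", "external_stub"))
  if (!dim %in% 1:3) abort("`dim` must be 1, 2 or 3.")
  params <- validate_backend_params(backend, params)
  if (is.null(n_particles)) {
    n_coords <- backend_n_coords(backend, params)
    if (is.null(n_coords)) {
      abort("`n_particles` must be given for this backend.")
    }
    if (n_coords %% dim != 0) {
      abort("Backend coordinate count is not a multiple of `dim`.")
    }
    n_particles <- n_coords %/% dim
  }
  if (!is.numeric(n_particles) || length(n_particles) != 1 ||
      n_particles < 1 || n_particles != round(n_particles)) {
    abort("`n_particles` must be a positive integer.")
  }
  n_particles <- as.integer(n_particles)
  masses <- rep_len(as.numeric(masses), n_particles)
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    abort("All masses must be finite and > 0.")
  }
  frozen <- rep_len(as.logical(frozen), n_particles)
  if (anyNA(frozen)) abort("`frozen` must be TRUE/FALSE per particle.")
  n_coords <- backend_n_coords(backend, params)
  if (!is.null(n_coords) && n_coords != n_particles * dim) {
    abort(sprintf(
      "Backend parameters describe %d coordinates but n_particles * dim = %d.",
      n_coords, n_particles * dim))
  }
  structure(
    list(backend = backend, params = params, n_particles = n_particles,
         dim = dim, masses = masses, frozen = frozen),
    class = "two_state_system")
}

#' @export
print.two_state_system <- function(x, ...) {
  cat(sprintf("<two_state_system> backend: %s\n", x$backend))
  cat(sprintf("  %d particle(s) x %dD (%d coordinates), %d frozen\n",
              x$n_particles, x$dim, n_coords(x), sum(x$frozen)))
  invisible(x)
}

# total coordinate count of a system
n_coords <- function(system) system$n_particles * system$dim

# per-coordinate expansion of per-particle vectors
coord_masses <- function(system) rep(system$masses, each = system$dim)
coord_frozen <- function(system) rep(system$frozen, each = system$dim)

# number of coordinates implied by the backend params (NULL if free)
backend_n_coords <- function(backend, params) {
  switch(backend,
    harmonic_pair = length(params$k_s),
    quartic_pair = length(params$a4_s),
    noisy_environment = length(params$solute$k_s) + params$n_env,
    external_stub = params$n_coords %||% NULL)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

validate_backend_params <- function(backend, params) {
  switch(backend,
    harmonic_pair = validate_harmonic_params(params),
    quartic_pair = validate_quartic_params(params),
    noisy_environment = {
      req <- c("solute", "n_env", "env_k")
      missing <- setdiff(req, names(params))
      if (length(missing)) {
        abort(paste0("noisy_environment backend requires parameters: ",
                     paste(missing, collapse = ", ")))
      }
      params$solute <- validate_harmonic_params(params$solute)
      if (params$n_env < 1 || params$n_env != round(params$n_env)) {
        abort("`n_env` must be a positive integer.")
      }
      params$n_env <- as.integer(params$n_env)
      if (!is.numeric(params$env_k) || length(params$env_k) != 1 ||
          params$env_k <= 0) {
        abort("`env_k` must be a single positive force constant.")
      }
      params
    },
    external_stub = params)
}

validate_harmonic_params <- function(params) {
  req <- c("k_s", "k_t", "x0_s", "x0_t", "e0_s", "e0_t")
  missing <- setdiff(req, names(params))
  if (length(missing)) {
    abort(paste0("harmonic_pair backend requires parameters: ",
                 paste(missing, collapse = ", ")))
  }
  nc <- length(params$k_s)
  for (nm in c("k_t", "x0_s", "x0_t")) {
    params[[nm]] <- rep_len(as.numeric(params[[nm]]), nc)
  }
  params$k_s <- as.numeric(params$k_s)
  for (nm in c("e0_s", "e0_t")) {
    if (length(params[[nm]]) != 1) abort(sprintf("`%s` must be scalar.", nm))
    params[[nm]] <- as.numeric(params[[nm]])
  }
  if (any(params$k_s <= 0) || any(params$k_t <= 0)) {
    abort("All force constants must be > 0.")
  }
  params[req]
}

validate_quartic_params <- function(params) {
  req <- c("a4_s", "a4_t", "a2_s", "a2_t", "x0_s", "x0_t", "e0_s", "e0_t")
  missing <- setdiff(req, names(params))
  if (length(missing)) {
    abort(paste0("quartic_pair backend requires parameters: ",
                 paste(missing, collapse = ", ")))
  }
  nc <- length(params$a4_s)
  for (nm in c("a4_t", "a2_s", "a2_t", "x0_s", "x0_t")) {
    params[[nm]] <- rep_len(as.numeric(params[[nm]]), nc)
  }
  params$a4_s <- as.numeric(params$a4_s)
  for (nm in c("e0_s", "e0_t")) {
    if (length(params[[nm]]) != 1) abort(sprintf("`%s` must be scalar.", nm))
    params[[nm]] <- as.numeric(params[[nm]])
  }
  if (any(params$a4_s < 0) || any(params$a4_t < 0)) {
    abort("Quartic coefficients must be >= 0.")
  }
  params[req]
}

check_coords <- function(system, x) {
  x <- as.numeric(x)
  if (length(x) != n_coords(system)) {
    abort(sprintf("`x` must have %d coordinates, got %d.",
                  n_coords(system), length(x)))
  }
  if (any(!is.finite(x))) abort("`x` contains non-finite coordinates.")
  x
}

#' Energy and gradient of one electronic state
#'
#' Evaluates the backend's potential energy surface for the singlet or triplet
#' state at configuration `x`. The gradient is the exact analytic derivative of
#' the returned energy; frozen coordinates still report their gradient (the
#' mask is applied by the dynamics, not the backend).
#'
#' @param system A [two_state_system()].
#' @param x Numeric coordinates (A), length `n_particles * dim`.
#' @param state `"singlet"` or `"triplet"`.
#' @return A list with `energy` (kJ/mol) and `gradient` (kJ/mol/A, same length
#'   as `x`).
#' @export
state_energy <- function(system, x, state = c("singlet", "triplet")) {
  state <- match.arg(state)
  x <- check_coords(system, x)
  if (system$backend == "external_stub") {
    abort(paste0(
      "external_stub backend cannot be evaluated: it documents the contract ",
      "an external engine adapter must satisfy (energy + gradient for both ",
      "spin states per call)."), class = "spinfep_unsupported_backend")
  }
  backend_energy(system, x, state)
}

backend_energy <- function(system, x, state) {
  p <- system$params
  switch(system$backend,
    harmonic_pair = harmonic_energy(p, x, state),
    quartic_pair = quartic_energy(p, x, state),
    noisy_environment = {
      ns <- length(p$solute$k_s)
      xs <- x[seq_len(ns)]
      xe <- x[-seq_len(ns)]
      sol <- harmonic_energy(p$solute, xs, state)
      # common-mode environment term, identical for both electronic states
      e_env <- 0.5 * p$env_k * sum(xe^2)
      g_env <- p$env_k * xe
      list(energy = sol$energy + e_env, gradient = c(sol$gradient, g_env))
    })
}

harmonic_energy <- function(p, x, state) {
  if (state == "singlet") {
    k <- p$k_s; x0 <- p$x0_s; e0 <- p$e0_s
  } else {
    k <- p$k_t; x0 <- p$x0_t; e0 <- p$e0_t
  }
  d <- x - x0
  list(energy = e0 + 0.5 * sum(k * d^2), gradient = k * d)
}

quartic_energy <- function(p, x, state) {
  if (state == "singlet") {
    a4 <- p$a4_s; a2 <- p$a2_s; x0 <- p$x0_s; e0 <- p$e0_s
  } else {
    a4 <- p$a4_t; a2 <- p$a2_t; x0 <- p$x0_t; e0 <- p$e0_t
  }
  d <- x - x0
  list(energy = e0 + sum(a4 * d^4 + a2 * d^2),
       gradient = 4 * a4 * d^3 + 2 * a2 * d)
}

#' Lambda-mixed alchemical energy and gradient
#'
#' Evaluates the mixed Hamiltonian \eqn{H(\lambda) = (1-\lambda) H_S + \lambda
#' H_T} and its gradient at configuration `x`. Both pure-state energies are
#' returned alongside the mixture, so every sampled frame carries
#' \eqn{(E_S, E_T, E_{mix})} and free-energy post-processing never needs to
#' re-evaluate the backend.
#'
#' At the endpoints the mixture is exact: `lambda = 0` returns the singlet
#' energy and gradient bit-identically, `lambda = 1` the triplet.
#'
#' @inheritParams state_energy
#' @param lambda Mixing parameter in \[0, 1\].
#' @return A list with `energy`, `gradient`, `e_singlet`, `e_triplet`.
#' @export
mixed_energy <- function(system, x, lambda) {
  check_lambda(lambda)
  x <- check_coords(system, x)
  if (system$backend == "external_stub") {
    abort("external_stub backend cannot be evaluated.",
          class = "spinfep_unsupported_backend")
  }
  s <- backend_energy(system, x, "singlet")
  t <- backend_energy(system, x, "triplet")
  if (lambda == 0) {
    list(energy = s$energy, gradient = s$gradient,
         e_singlet = s$energy, e_triplet = t$energy)
  } else if (lambda == 1) {
    list(energy = t$energy, gradient = t$gradient,
         e_singlet = s$energy, e_triplet = t$energy)
  } else {
    list(energy = (1 - lambda) * s$energy + lambda * t$energy,
         gradient = (1 - lambda) * s$gradient + lambda * t$gradient,
         e_singlet = s$energy, e_triplet = t$energy)
  }
}

check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda) ||
      lambda < 0 || lambda > 1) {
    abort("`lambda` must be a single value in [0, 1].")
  }
  invisible(lambda)
}
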