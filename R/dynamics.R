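#' Molecular-dynamics run configuration
#'
#' Parameters controlling one sampling window of the mixed Hamiltonian.
#' Units follow the package convention: `dt` in fs, `temperature` in K,
#' `friction` in ps^-1.
#'
#' @param n_steps Total integration steps.
#' @param dt Timestep in fs.
#' @param n_equil Equilibration steps discarded from the front of the run
#'   (default 10\% of `n_steps`).
#' @param temperature Thermostat target temperature in K.
#' @param friction Langevin friction in ps^-1; `friction = 0` disables the
#'   stochastic/thermostat step entirely (NVE diagnostic mode).
#' @param seed Integer seed; runs are bit-reproducible given the seed.
#' @param record_stride Record every `record_stride`-th post-equilibration
#'   frame.
#' @param record_velocities Keep per-frame velocities (needed for
#'   [kinetic_temperature()]).
#' @param record_coords Keep per-frame coordinates.
#' @return A list of class `md_config`.
#' @export
md_config <- function(n_steps, dt = 1, n_equil = ceiling(0.1 * n_steps),
                      temperature = 300, friction = 1, seed = 1L,
                      record_stride = 1L, record_velocities = FALSE,
                      record_coords = FALSE) {
  stopifnot(dt > 0, n_steps >= 1, n_equil >= 0, n_steps > n_equil,
            temperature > 0, friction >= 0, record_stride >= 1)
  structure(list(n_steps = as.integer(n_steps), dt = dt,
                 n_equil = as.integer(n_equil), temperature = temperature,
                 friction = friction, seed = as.integer(seed),
                 record_stride = as.integer(record_stride),
                 record_velocities = record_velocities,
                 record_coords = record_coords),
            class = "md_config")
}

#' Construct an energy series
#'
#' An `energy_series` is a tibble of per-frame energies sampled from one
#' lambda window -- columns `step`, `e_singlet`, `e_triplet`, `e_mix` -- with
#' the window's `lambda`, `temperature` and `seed` attached as attributes.
#' The affine-mix identity `e_mix = (1-lambda) e_singlet + lambda e_triplet`
#' is checked on construction (tolerance 1e-9 relative to the energy scale).
#'
#' @param frames Tibble or data frame with columns `step`, `e_singlet`,
#'   `e_triplet`, `e_mix`.
#' @param lambda Lambda of the sampling Hamiltonian.
#' @param temperature Sampling temperature in K.
#' @param seed Seed the series was generated with (or `NA`).
#' @param coords Optional per-frame coordinate matrix (frames x coordinates).
#' @param velocities Optional per-frame velocity matrix.
#' @return A tibble of class `energy_series`.
#' @export
energy_series <- function(frames, lambda, temperature, seed = NA_integer_,
                          coords = NULL, velocities = NULL) {
  check_lambda(lambda)
  stopifnot(temperature > 0)
  frames <- as_tibble(frames)
  req <- c("step", "e_singlet", "e_triplet", "e_mix")
  if (!all(req %in% names(frames))) {
    abort(paste0("`frames` must have columns: ", paste(req, collapse = ", ")))
  }
  if (nrow(frames) == 0) abort("`frames` must be non-empty.")
  if (is.unsorted(frames$step)) abort("Frames must be ordered by step.")
  mix <- (1 - lambda) * frames$e_singlet + lambda * frames$e_triplet
  scale <- pmax(1, abs(frames$e_mix))
  if (any(abs(mix - frames$e_mix) > 1e-9 * scale)) {
    abort("e_mix does not satisfy the affine-mix identity within 1e-9.")
  }
  structure(frames, lambda = lambda, temperature = temperature,
            seed = seed, coords = coords, velocities = velocities,
            class = c("energy_series", class(frames)))
}

#' @export
print.energy_series <- function(x, ...) {
  cat(sprintf("<energy_series> lambda = %g, T = %g K, %d frames\n",
              series_lambda(x), series_temperature(x), nrow(x)))
  NextMethod()
}

#' Accessors for energy-series metadata
#'
#' @param series An [energy_series()].
#' @return The window's lambda, temperature (K) or seed.
#' @export
series_lambda <- function(series) attr(series, "lambda")

#' @rdname series_lambda
#' @export
series_temperature <- function(series) attr(series, "temperature")

#' @rdname series_lambda
#' @export
series_seed <- function(series) attr(series, "seed")

# derive an independent, reproducible stream seed for window index i (1-based)
# from the master seed; kept below 2^31
window_seed <- function(master_seed, i) {
  (as.integer(master_seed) %% 2003819L) * 1009L + 7919L * as.integer(i)
}

#' Sample one lambda window by Langevin dynamics
#'
#' Propagates the mixed Hamiltonian \eqn{H(\lambda)} at fixed temperature with
#' the BAOAB splitting of Langevin dynamics, and records per-frame
#' \eqn{(E_S, E_T, E_{mix})} after discarding the equilibration segment.
#' Frozen particles keep zero velocity and zero displacement for the whole
#' run. With `friction = 0` the O-step is the identity and the integrator
#' reduces to velocity Verlet (NVE diagnostic mode: no thermostat noise).
#'
#' Initial coordinates default to the mixed-state minimum for harmonic-family
#' backends and to the singlet minimum for quartic ones; initial velocities of
#' mobile particles are Maxwell-Boltzmann draws at the target temperature.
#'
#' @param system A [two_state_system()] with an evaluable backend.
#' @param lambda Mixing parameter of the sampling Hamiltonian.
#' @param config An [md_config()].
#' @param x0 Optional starting coordinates (length `n_particles * dim`).
#' @return An [energy_series()].
#' @export
run_window <- function(system, lambda, config, x0 = NULL) {
  check_lambda(lambda)
  stopifnot(inherits(config, "md_config"))
  if (system$backend == "external_stub") {
    abort("external_stub backend cannot be propagated.",
          class = "spinfep_unsupported_backend")
  }
  nc <- n_coords(system)
  m <- coord_masses(system)
  frozen <- coord_frozen(system)
  mobile <- !frozen
  if (all(frozen) && is.null(x0)) {
    abort("All particles frozen and no `x0` given: nothing defines the geometry.")
  }
  x <- if (is.null(x0)) default_x0(system, lambda) else check_coords(system, x0)

  dt <- config$dt
  kbt <- kT(config$temperature)
  # internal unit conversions: time unit = 100 fs (kJ/mol, A, amu)
  dt_i <- dt / .time_unit_fs
  gamma_i <- config$friction / 1000 * .time_unit_fs  # ps^-1 -> per time unit

  withr::local_seed(config$seed)
  v <- numeric(nc)
  if (any(mobile)) {
    v[mobile] <- rnorm(sum(mobile), 0, sqrt(kbt / m[mobile]))  # internal units
  }
  c1 <- exp(-gamma_i * dt_i)
  c2 <- if (config$friction > 0) sqrt((1 - c1^2) * kbt / m) else numeric(nc)

  ev <- mixed_energy(system, x, lambda)
  f <- -ev$gradient
  f[frozen] <- 0

  n_rec <- length(seq.int(config$n_equil + 1L, config$n_steps,
                          by = config$record_stride))
  rec_step <- integer(n_rec); rec_es <- numeric(n_rec)
  rec_et <- numeric(n_rec); rec_em <- numeric(n_rec)
  rec_x <- if (config$record_coords) matrix(NA_real_, n_rec, nc) else NULL
  rec_v <- if (config$record_velocities) matrix(NA_real_, n_rec, nc) else NULL
  j <- 0L

  for (step in seq_len(config$n_steps)) {
    # B
    v <- v + 0.5 * dt_i * f / m
    v[frozen] <- 0
    # A
    x <- x + 0.5 * dt_i * v
    # O
    if (config$friction > 0) {
      v <- c1 * v + c2 * rnorm(nc)
      v[frozen] <- 0
    }
    # A
    x <- x + 0.5 * dt_i * v
    # B with fresh force
    ev <- mixed_energy(system, x, lambda)
    if (!is.finite(ev$energy) || any(!is.finite(ev$gradient))) {
      abort(sprintf("Dynamics diverged at step %d (non-finite energy/force).",
                    step), class = "spinfep_divergence_error")
    }
    f <- -ev$gradient
    f[frozen] <- 0
    v <- v + 0.5 * dt_i * f / m
    v[frozen] <- 0

    if (step > config$n_equil &&
        (step - config$n_equil - 1L) %% config$record_stride == 0L) {
      j <- j + 1L
      rec_step[j] <- step
      rec_es[j] <- ev$e_singlet
      rec_et[j] <- ev$e_triplet
      rec_em[j] <- ev$energy
      if (!is.null(rec_x)) rec_x[j, ] <- x
      if (!is.null(rec_v)) rec_v[j, ] <- v
    }
  }

  energy_series(
    tibble(step = rec_step, e_singlet = rec_es, e_triplet = rec_et,
           e_mix = rec_em),
    lambda = lambda, temperature = config$temperature, seed = config$seed,
    coords = rec_x, velocities = rec_v)
}

default_x0 <- function(system, lambda) {
  p <- system$params
  switch(system$backend,
    harmonic_pair = mixed_minimum(p, lambda),
    noisy_environment = c(mixed_minimum(p$solute, lambda), rep(0, p$n_env)),
    quartic_pair = p$x0_s,
    abort("No default geometry for this backend."))
}

# minimum of the lambda-mixed harmonic potential, per coordinate
mixed_minimum <- function(p, lambda) {
  k_eff <- (1 - lambda) * p$k_s + lambda * p$k_t
  ((1 - lambda) * p$k_s * p$x0_s + lambda * p$k_t * p$x0_t) / k_eff
}

#' Exact canonical sampling of a harmonic mixed state
#'
#' For harmonic-family backends the lambda-mixed potential is itself harmonic
#' (an affine combination of quadratics), so the canonical distribution is a
#' product of per-coordinate Gaussians with effective force constant
#' \eqn{k_{eff} = (1-\lambda) k_S + \lambda k_T} centred on the mixed minimum.
#' This draws `n` independent exact samples from it -- no dynamics, no
#' equilibration, no serial correlation -- and returns the same
#' [energy_series()] contract as [run_window()]. Frozen coordinates are pinned
#' at the mixed minimum.
#'
#' @inheritParams run_window
#' @param temperature Temperature in K.
#' @param n Number of independent draws.
#' @param seed Integer seed.
#' @return An [energy_series()] of `n` frames.
#' @export
direct_canonical_sample <- function(system, lambda, temperature, n, seed = 1L) {
  check_lambda(lambda)
  stopifnot(temperature > 0, n >= 1)
  if (!system$backend %in% c("harmonic_pair", "noisy_environment")) {
    abort(sprintf(
      "direct_canonical_sample requires a harmonic backend, got '%s'.",
      system$backend), class = "spinfep_unsupported_backend")
  }
  p <- system$params
  if (system$backend == "harmonic_pair") {
    k_s <- p$k_s; k_t <- p$k_t; x0s <- p$x0_s; x0t <- p$x0_t
  } else {
    k_s <- c(p$solute$k_s, rep(p$env_k, p$n_env))
    k_t <- c(p$solute$k_t, rep(p$env_k, p$n_env))
    x0s <- c(p$solute$x0_s, rep(0, p$n_env))
    x0t <- c(p$solute$x0_t, rep(0, p$n_env))
  }
  k_eff <- (1 - lambda) * k_s + lambda * k_t
  mu <- ((1 - lambda) * k_s * x0s + lambda * k_t * x0t) / k_eff
  sdv <- sqrt(kT(temperature) / k_eff)
  frozen <- coord_frozen(system)
  sdv[frozen] <- 0

  nc <- n_coords(system)
  withr::local_seed(as.integer(seed))
  xs <- matrix(rnorm(n * nc, 0, 1), nrow = n) *
    matrix(sdv, n, nc, byrow = TRUE) + matrix(mu, n, nc, byrow = TRUE)

  e0s <- if (system$backend == "harmonic_pair") p$e0_s else p$solute$e0_s
  e0t <- if (system$backend == "harmonic_pair") p$e0_t else p$solute$e0_t
  ds <- sweep(xs, 2, x0s); dt_ <- sweep(xs, 2, x0t)
  e_s <- e0s + 0.5 * as.vector(ds^2 %*% k_s)
  e_t <- e0t + 0.5 * as.vector(dt_^2 %*% k_t)
  e_m <- (1 - lambda) * e_s + lambda * e_t
  energy_series(
    tibble(step = seq_len(n), e_singlet = e_s, e_triplet = e_t, e_mix = e_m),
    lambda = lambda, temperature = temperature, seed = as.integer(seed),
    coords = xs)
}

#' Kinetic temperature of a velocity series
#'
#' Computes the instantaneous kinetic temperature \eqn{T = \sum m v^2 / (N_f
#' k_B)} per frame over the non-frozen degrees of freedom, and its mean --
#' the standard thermostat diagnostic. Frozen particles are excluded even if
#' their stored velocities are nonzero.
#'
#' @param velocities Numeric matrix, frames x coordinates (internal velocity
#'   units, as recorded by [run_window()]), or an [energy_series()] recorded
#'   with `record_velocities = TRUE`.
#' @param masses Per-particle masses in amu.
#' @param frozen Logical per-particle frozen mask.
#' @param dim Spatial dimension per particle.
#' @return A list with `mean` (K) and `per_frame` (vector of K).
#' @export
kinetic_temperature <- function(velocities, masses, frozen = FALSE, dim = 1) {
  if (inherits(velocities, "energy_series")) {
    velocities <- attr(velocities, "velocities")
  }
  if (is.null(velocities)) {
    abort("No velocity records present (run with record_velocities = TRUE).")
  }
  velocities <- as.matrix(velocities)
  n_part <- ncol(velocities) / dim
  masses <- rep_len(as.numeric(masses), n_part)
  frozen <- rep_len(as.logical(frozen), n_part)
  mobile <- !rep(frozen, each = dim)
  n_dof <- sum(mobile)
  if (n_dof == 0) {
    abort("All particles frozen: kinetic temperature undefined.",
          class = "spinfep_undefined_temperature")
  }
  m <- rep(masses, each = dim)[mobile]
  per_frame <- as.vector(velocities[, mobile, drop = FALSE]^2 %*% m) /
    (n_dof * k_boltzmann)
  list(mean = mean(per_frame), per_frame = per_frame)
}

#' Write recorded coordinates as a standard XYZ trajectory
#'
#' Emits the coordinate records of an [energy_series()] (run with
#' `record_coords = TRUE`) as multi-frame XYZ text: atom count, a comment
#' line carrying the step and mixed energy, then one `element x y z` line
#' per particle. Particles in fewer than 3 dimensions are padded with zeros.
#'
#' @param series An [energy_series()] with coordinate records.
#' @param path Output file path.
#' @param elements Element symbols per particle (recycled).
#' @param dim Spatial dimension per particle used when the series was
#'   sampled (coordinates are stored flat).
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(series, path, elements = "X", dim = 1) {
  stopifnot(inherits(series, "energy_series"), dim %in% 1:3)
  xs <- attr(series, "coords")
  if (is.null(xs)) abort("No coordinate records (run with record_coords = TRUE).")
  xs <- as.matrix(xs)
  n_frames <- nrow(xs)
  nc <- ncol(xs)
  if (nc %% dim != 0) abort("Coordinate count is not a multiple of `dim`.")
  n_part <- nc %/% dim
  elements <- rep_len(elements, n_part)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames)) {
    writeLines(as.character(n_part), con)
    writeLines(sprintf("step %d e_mix %.10g", series$step[f],
                       series$e_mix[f]), con)
    xyz <- matrix(0, n_part, 3)
    xyz[, seq_len(dim)] <- matrix(xs[f, ], n_part, dim, byrow = TRUE)
    writeLines(sprintf("%s %.10f %.10f %.10f", elements,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Maxwell-Boltzmann velocity draws
#'
#' Draws per-coordinate velocities at temperature `T` in the package's
#' internal velocity unit (A per 100 fs). Mainly a helper for thermostat
#' diagnostics and tests.
#'
#' @param n_frames Number of frames.
#' @param masses Per-particle masses (amu).
#' @param temperature Temperature in K.
#' @param dim Spatial dimension per particle.
#' @param seed Integer seed.
#' @return Matrix of `n_frames` x `length(masses) * dim` velocities.
#' @export
maxwell_boltzmann_velocities <- function(n_frames, masses, temperature,
                                         dim = 1, seed = 1L) {
  m <- rep(as.numeric(masses), each = dim)
  withr::local_seed(as.integer(seed))
  matrix(rnorm(n_frames * length(m)), nrow = n_frames) *
    matrix(sqrt(kT(temperature) / m), n_frames, length(m), byrow = TRUE)
}
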