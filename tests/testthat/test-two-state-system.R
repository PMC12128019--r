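test_that("harmonic state energies follow the closed form", {
  sys <- two_state_system("harmonic_pair", params = list(
    k_s = 1, k_t = 2, x0_s = 0, x0_t = 1, e0_s = 0, e0_t = 10))
  # 1/2 k x^2 at x = 2
  se <- state_energy(sys, 2, "singlet")
  expect_identical(se$energy, 2)
  expect_identical(se$gradient, 2)
  # each state's minimum returns its offset with zero gradient
  expect_equal(state_energy(sys, 0, "singlet"),
               list(energy = 0, gradient = 0))
  expect_equal(state_energy(sys, 1, "triplet"),
               list(energy = 10, gradient = 0))
})

test_that("analytic gradients match central finite differences", {
  withr::local_seed(42)
  step <- 1e-5
  for (sys in list(harmonic_1d(), quartic_1d(),
                   make_noisy_environment(5, solute = list(
                     k_s = 2, k_t = 3, x0_s = 0, x0_t = 0.3,
                     e0_s = 0, e0_t = 7)))) {
    nc <- sys$n_particles * sys$dim
    for (rep in 1:5) {
      x <- rnorm(nc, 0, 1)
      for (state in c("singlet", "triplet")) {
        ev <- state_energy(sys, x, state)
        g_num <- vapply(seq_len(nc), function(i) {
          xp <- x; xm <- x
          xp[i] <- x[i] + step; xm[i] <- x[i] - step
          (state_energy(sys, xp, state)$energy -
             state_energy(sys, xm, state)$energy) / (2 * step)
        }, numeric(1))
        expect_equal(ev$gradient, g_num, tolerance = 1e-6)
      }
    }
  }
})

test_that("mixed energy is exact at the endpoints and affine in lambda", {
  sys <- quartic_1d()
  withr::local_seed(7)
  for (x in rnorm(5, 0, 1.5)) {
    s <- state_energy(sys, x, "singlet")
    t <- state_energy(sys, x, "triplet")
    m0 <- mixed_energy(sys, x, 0)
    m1 <- mixed_energy(sys, x, 1)
    # bit-identical endpoint reduction
    expect_identical(m0$energy, s$energy)
    expect_identical(m0$gradient, s$gradient)
    expect_identical(m1$energy, t$energy)
    expect_identical(m1$gradient, t$gradient)
    # affinity: collinearity residual across 11 lambda points
    lams <- seq(0, 1, by = 0.1)
    e <- vapply(lams, function(l) mixed_energy(sys, x, l)$energy, numeric(1))
    resid <- e - (e[1] + (e[11] - e[1]) * lams)
    expect_lt(max(abs(resid)), 1e-12 * max(1, abs(e[1]), abs(e[11])))
    # every evaluation carries both pure-state energies
    expect_identical(m0$e_triplet, t$energy)
    expect_identical(m1$e_singlet, s$energy)
  }
})

test_that("mixing at lambda 0.5 averages the two state energies", {
  sys <- two_state_system("harmonic_pair", params = list(
    k_s = 1, k_t = 1, x0_s = 0, x0_t = 0, e0_s = 2, e0_t = 4))
  expect_equal(mixed_energy(sys, 0, 0.5)$energy, 3)
})

test_that("input validation rejects bad systems, coordinates and lambdas", {
  sys <- harmonic_1d()
  expect_error(state_energy(sys, c(1, 2), "singlet"), "coordinates")
  expect_error(mixed_energy(sys, 1, -0.1), "lambda")
  expect_error(mixed_energy(sys, 1, 1.2), "lambda")
  expect_error(two_state_system("harmonic_pair",
                                params = list(k_s = 1)), "requires")
  expect_error(two_state_system("harmonic_pair", params = list(
    k_s = -1, k_t = 1, x0_s = 0, x0_t = 0, e0_s = 0, e0_t = 0)),
    "force constants")
  expect_error(two_state_system("harmonic_pair", params = list(
    k_s = 1, k_t = 1, x0_s = 0, x0_t = 0, e0_s = 0, e0_t = 0),
    masses = 0), "masses")
  stub <- two_state_system("external_stub", params = list(n_coords = 1))
  expect_error(state_energy(stub, 0, "singlet"),
               class = "spinfep_unsupported_backend")
})

test_that("analytic and quadrature free energies agree on harmonic pairs", {
  # identical widths: dF is the pure offset
  same <- two_state_system("harmonic_pair", params = list(
    k_s = 1, k_t = 1, x0_s = 0, x0_t = 2, e0_s = 0, e0_t = 10))
  expect_equal(analytic_delta_f(same, 300), 10)
  # k_t = k_s * e^2 at equal offsets: dF = kB T
  ratio <- two_state_system("harmonic_pair", params = list(
    k_s = 1, k_t = exp(2), x0_s = 0, x0_t = 0, e0_s = 0, e0_t = 0))
  expect_equal(analytic_delta_f(ratio, 300), k_boltzmann * 300,
               tolerance = 1e-12)
  # mixed 2-coordinate case against the quadrature oracle
  mixed <- two_state_system("harmonic_pair", params = list(
    k_s = c(1, 2), k_t = c(3, 0.7), x0_s = c(0, 0.5), x0_t = c(1, -0.5),
    e0_s = 0, e0_t = 10))
  expect_equal(quadrature_delta_f(mixed, 300),
               analytic_delta_f(mixed, 300), tolerance = 1e-6)
  expect_equal(quadrature_delta_f(harmonic_1d(), 300),
               analytic_delta_f(harmonic_1d(), 300), tolerance = 1e-6)
})

test_that("quadrature handles degenerate and anharmonic cases", {
  # identical backends: exactly zero free-energy difference
  expect_equal(quadrature_delta_f(null_pair(), 300), 0, tolerance = 1e-10)
  # harmonic singlet vs quartic triplet: regression value frozen after the
  # first verified computation (stable under grid refinement)
  qsys <- two_state_system("quartic_pair", params = list(
    a4_s = 0, a4_t = 0.25, a2_s = 0.5, a2_t = 0.5,
    x0_s = 0, x0_t = 0, e0_s = 0, e0_t = 5))
  expect_equal(quadrature_delta_f(qsys, 300), 5.98715790511,
               tolerance = 1e-9)
  # a grid that stops short of the wells' tails is refused
  expect_error(quadrature_delta_f(harmonic_1d(), 300, half_width_sd = 8,
                                  boundary_tol = 1e-16),
               class = "spinfep_accuracy_error")
  expect_error(quadrature_delta_f(null_pair(3), 300), "at most 2")
})
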