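# Shared in-code fixtures for the test suite. Everything is generated from
# explicit parameters and seeds; no files are read.

default_schedule <- c(0, 0.2, 0.4, 0.6, 0.8, 1)

# 1D harmonic two-state pair with distinct widths and offset minima
harmonic_1d <- function(k_t = 2, de0 = 10, x0_t = 0.5) {
  two_state_system("harmonic_pair", params = list(
    k_s = 1, k_t = k_t, x0_s = 0, x0_t = x0_t, e0_s = 0, e0_t = de0))
}

# quartic pair with anharmonic wells in both states
quartic_1d <- function() {
  two_state_system("quartic_pair", params = list(
    a4_s = 0.1, a4_t = 0.25, a2_s = 0.5, a2_t = 0.3,
    x0_s = -0.2, x0_t = 0.4, e0_s = 0, e0_t = 5))
}

# identical singlet and triplet surfaces: the null perturbation
null_pair <- function(n_coords = 1) {
  two_state_system("harmonic_pair", params = list(
    k_s = rep(1.5, n_coords), k_t = rep(1.5, n_coords),
    x0_s = rep(0.1, n_coords), x0_t = rep(0.1, n_coords),
    e0_s = 3, e0_t = 3))
}

# exact canonical series over a schedule, one independent seed per window
exact_series <- function(system, n, seed, schedule = default_schedule,
                         temperature = 300) {
  lapply(seq_along(schedule), function(i) {
    direct_canonical_sample(system, schedule[i], temperature, n,
                            seed = seed * 101 + i)
  })
}
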