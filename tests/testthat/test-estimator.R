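test_that("the Zwanzig estimator is exact for degenerate gap series", {
  # null perturbation
  expect_identical(zwanzig_dg(window_record(rep(0, 50), 0, 1, 300)), 0)
  # constant shift passes through exactly, including huge gaps
  for (c0 in c(-3, 40, 1e4, -1e4)) {
    expect_equal(zwanzig_dg(window_record(rep(c0, 50), 0, 1, 300)), c0,
                 tolerance = 1e-12)
  }
  expect_error(window_record(numeric(0), 0, 1, 300), "non-empty")
  expect_error(window_record(c(1, NaN), 0, 1, 300), "finite")
})

test_that("the Zwanzig estimate converges to the Gaussian closed form", {
  rec <- generate_gaussian_dh(mu = 5, sigma = 2, n = 2e5, seed = 101)
  err <- chipot_error(rec)
  expect_lt(abs(zwanzig_dg(rec) - gaussian_dg_limit(5, 2, 300)),
            3 * err$eps)
})

test_that("exponential averaging never exceeds the arithmetic mean", {
  # Jensen bound, over assorted gap distributions
  withr::local_seed(202)
  for (i in 1:20) {
    dh <- switch(1 + i %% 4,
      rnorm(500, runif(1, -5, 5), runif(1, 0, 10)),
      stats::rexp(500, 0.2) - 2,
      stats::runif(500, -20, 20),
      stats::rt(500, df = 5) * 3)
    rec <- window_record(dh, 0, 0.5, 300)
    expect_lte(zwanzig_dg(rec), mean(dh) + 1e-10)
  }
})

test_that("lag-1 autocorrelation handles degenerate and known cases", {
  expect_identical(lag1_autocorrelation(rep(2.5, 10)), 0)
  alt <- rep(c(1, -1), 50)
  expect_equal(lag1_autocorrelation(alt), -1, tolerance = 0.02)
  r1 <- lag1_autocorrelation(generate_ar1(0.5, 1e5, seed = 7))
  expect_lt(abs(r1 - 0.5), 0.02)
  r0 <- lag1_autocorrelation(generate_ar1(0, 1e4, seed = 8))
  expect_lt(abs(r0), 3 / sqrt(1e4))
  expect_error(lag1_autocorrelation(c(1, 2)), "at least 3")
})

test_that("sampling ratio follows its closed form", {
  expect_identical(sampling_ratio(0), 1)
  expect_equal(sampling_ratio(0.5), 3)
  expect_equal(sampling_ratio(-0.5), 1 / 3)
  expect_error(sampling_ratio(1), "inside")
  expect_error(sampling_ratio(-1.2), "inside")
  # estimated ratio on an AR(1) series with rho = 0.5
  r1 <- lag1_autocorrelation(generate_ar1(0.5, 1e5, seed = 12))
  expect_lt(abs(sampling_ratio(r1) - 3) / 3, 0.1)
})

test_that("the first-order error is calibrated against replicate spread", {
  expect_equal(chipot_error(window_record(rep(7, 100), 0, 1, 300))$eps, 0)
  # IID replicates: mean predicted error within 1.5x of the empirical SD
  dgs <- numeric(60); eps <- numeric(60)
  for (i in 1:60) {
    rec <- generate_gaussian_dh(2, 1, 3000, seed = 400 + i)
    dgs[i] <- zwanzig_dg(rec)
    eps[i] <- chipot_error(rec)$eps
  }
  ratio <- mean(eps) / sd(dgs)
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
  expect_error(chipot_error(window_record(1, 0, 1, 300)), "at least 2")
})

test_that("serial correlation inflates the error by the sampling ratio", {
  # same marginal distribution, AR(1) correlation rho = 0.8: the corrected
  # error must exceed the IID-formula value by about sqrt((1+r1)/(1-r1))
  dh <- 2 + generate_ar1(0.8, 2e4, seed = 55)
  rec <- window_record(dh, 0, 1, 300)
  err <- chipot_error(rec)
  iid_eps <- err$eps / sqrt(err$sampling_ratio)
  expect_gt(err$eps / iid_eps, 2)   # ~ sqrt(9) = 3 for rho = 0.8
  expect_lt(err$eps / iid_eps, 4)
})

test_that("published-form toggles change the error model as documented", {
  rec <- generate_gaussian_dh(0.5, 0.3, 2000, seed = 77)
  default <- chipot_error(rec)
  printed <- chipot_error(rec, variance_form = "printed")
  multiplied <- chipot_error(rec, mean_position = "multiply")
  # <X> - <X>^2 is not the sample variance; the forms must differ
  expect_false(isTRUE(all.equal(default$eps, printed$eps)))
  # multiply-vs-divide differ by <X>^2
  kbt <- k_boltzmann * 300
  x_bar <- mean(exp(-rec$dh / kbt))
  expect_equal(multiplied$eps / default$eps, x_bar^2, tolerance = 1e-9)
})

test_that("window accumulation sums free energies and quadrature errors", {
  w <- tibble::tibble(
    lambda_from = c(0, 0.5), lambda_to = c(0.5, 1),
    dg = c(3, 4), eps = c(0.3, 0.4), r1 = 0, sampling_ratio = 1,
    n = 10L)
  res <- accumulate_windows(w)
  expect_identical(res$total_dg, 7)
  expect_equal(res$total_eps, 0.5)
  # six equal windows: 6 * 2 = 12 +/- sqrt(6 * 0.09)
  sched7 <- seq(0, 1, length.out = 7)
  w6 <- tibble::tibble(
    lambda_from = sched7[-7], lambda_to = sched7[-1],
    dg = 2, eps = 0.3)
  res6 <- accumulate_windows(w6)
  expect_identical(res6$total_dg, 12)
  expect_equal(res6$total_eps, sqrt(6 * 0.09))
  # single full window
  res1 <- accumulate_windows(tibble::tibble(
    lambda_from = 0, lambda_to = 1, dg = 5, eps = 0.1))
  expect_identical(res1$total_dg, 5)
  # gaps, overlaps and truncated schedules are refused
  bad <- w; bad$lambda_to[1] <- 0.4
  expect_error(accumulate_windows(bad), class = "spinfep_schedule_error")
  expect_error(accumulate_windows(w[1, ]), class = "spinfep_schedule_error")
})

test_that("schedule refinement leaves the harmonic total invariant", {
  sys <- harmonic_1d(k_t = exp(1.5), de0 = 10, x0_t = 0.4)
  res6 <- fep_estimate(exact_series(sys, 4000, seed = 61))
  sched11 <- seq(0, 1, by = 0.1)
  res11 <- fep_estimate(exact_series(sys, 4000, seed = 62,
                                     schedule = sched11))
  comb <- sqrt(res6$total_eps^2 + res11$total_eps^2)
  expect_lt(abs(res6$total_dg - res11$total_dg), 3 * comb)
})

test_that("identical backends give exactly zero in every window", {
  res <- fep_estimate(exact_series(null_pair(), 500, seed = 71))
  expect_true(all(res$windows$dg == 0))
  expect_identical(res$total_dg, 0)
})

test_that("window records derived from series obey the affine-gap identity", {
  sys <- harmonic_1d()
  s <- direct_canonical_sample(sys, 0.2, 300, 200, seed = 81)
  rec <- window_record_from_series(s, 0.4)
  expect_equal(rec$dh, 0.2 * (s$e_triplet - s$e_singlet))
  expect_equal(rec$lambda_from, 0.2)
  expect_equal(rec$lambda_to, 0.4)
  expect_error(window_record(1:3, 0.5, 0.5, 300), "distinct")
})

test_that("cross-temperature series are refused", {
  sys <- harmonic_1d()
  s1 <- direct_canonical_sample(sys, 0, 300, 100, seed = 1)
  s2 <- direct_canonical_sample(sys, 1, 320, 100, seed = 2)
  expect_error(fep_estimate(list(s1, s2)), "temperature")
})

test_that("endpoint Delta-U matches means and combines raw-data SDs", {
  mk <- function(e, lam) {
    energy_series(tibble::tibble(step = seq_along(e), e_singlet = e,
                                 e_triplet = e, e_mix = e),
                  lambda = lam, temperature = 300)
  }
  # identical constant ensembles
  r0 <- delta_u(mk(rep(5, 10), 0), mk(rep(5, 10), 1))
  expect_identical(r0$du, 0)
  expect_identical(r0$sd, 0)
  # constant offset
  r1 <- delta_u(mk(rep(100, 10), 0), mk(rep(140, 10), 1))
  expect_identical(r1$du, 40)
  # Gaussian energies with SD 40 each combine to sqrt(2) * 40
  withr::local_seed(91)
  rg <- delta_u(mk(rnorm(1000, 0, 40), 0), mk(rnorm(1000, 300, 40), 1))
  expect_lt(abs(rg$sd - sqrt(2) * 40) / (sqrt(2) * 40), 0.1)
  expect_error(delta_u(mk(rep(1, 5), 0), mk(rep(2, 5), 0.8)), "endpoint")
})

test_that("the overlap diagnostic separates converged from disjoint windows", {
  withr::local_seed(111)
  same_f <- window_record(rnorm(4000, 2, 1), 0, 0.2, 300)
  same_b <- window_record(-rnorm(4000, 2, 1), 0.2, 0, 300)
  ov <- window_overlap(same_f, same_b)
  expect_gt(ov$overlap, 0.9)
  disj <- window_overlap(window_record(rnorm(2000, 0, 0.5), 0, 0.2, 300),
                         window_record(rnorm(2000, 50, 0.5), 0.2, 0, 300))
  expect_lt(disj$overlap, 0.05)
  # converged harmonic windows close: |dg_fwd + dg_bwd| <= 3 (eps_f + eps_b)
  sys <- harmonic_1d(k_t = 2, de0 = 10, x0_t = 0.3)
  ser <- exact_series(sys, 4000, seed = 112)
  for (i in 1:5) {
    fwd <- window_record_from_series(ser[[i]], default_schedule[i + 1])
    bwd <- window_record_from_series(ser[[i + 1]], default_schedule[i])
    ov_i <- window_overlap(fwd, bwd)
    bound <- 3 * (chipot_error(fwd)$eps + chipot_error(bwd)$eps)
    expect_lt(abs(ov_i$discrepancy), bound)
  }
})

test_that("tidy and glance expose the per-window table and totals", {
  res <- fep_estimate(exact_series(harmonic_1d(), 500, seed = 121))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5)
  expect_named(td, c("lambda_from", "lambda_to", "dg", "eps", "r1",
                     "sampling_ratio", "n"))
  gl <- glance(res)
  expect_equal(gl$total_dg, res$total_dg)
  expect_equal(gl$n_windows, 5L)
  expect_equal(gl$n_samples, 2500L)
})
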