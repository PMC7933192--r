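# Monte Carlo microcell model: arrival statistics, recharge physics,
# settling, pile-up.

test_that("arrival generation follows a PDE-thinned Poisson process", {
  dev <- small_device(n = 50, pde = 1)

  # zero flux -> no events
  expect_length(simulate_arrivals(0, 1e-3, dev, seed = 1)$times, 0)

  # Poisson counting oracle: mean count over 100 seeds inside the 99%
  # normal band around flux * duration (pde = 1)
  lambda <- 1e9 * 1e-4
  counts <- vapply(1:100, function(s) {
    length(simulate_arrivals(1e9, 1e-4, dev, seed = s)$times)
  }, numeric(1))
  band <- qnorm(0.995) * sqrt(lambda / 100)
  expect_lt(abs(mean(counts) - lambda), band)

  # PDE thinning: detected / launched -> pde
  devp <- small_device(n = 50, pde = 0.3)
  n <- length(simulate_arrivals(1e9, 1e-3, devp, seed = 11)$times)
  expect_lt(abs(n / 1e6 - 0.3), qnorm(0.995) * sqrt(0.3 / 1e6) + 1e-3)

  # construction invariants and determinism
  arr <- simulate_arrivals(1e7, 1e-4, dev, seed = 3)
  expect_false(is.unsorted(arr$times))
  expect_true(all(arr$cell_ids >= 1 & arr$cell_ids <= dev$n_microcells))
  arr2 <- simulate_arrivals(1e7, 1e-4, dev, seed = 3)
  expect_identical(arr$times, arr2$times)
  expect_identical(arr$cell_ids, arr2$cell_ids)

  expect_error(simulate_arrivals(-1, 1e-3, dev), "flux")
  expect_error(simulate_arrivals(1e6, -1, dev), "duration")
})

test_that("single-cell recharge follows the closed-form RC law", {
  tau <- 20e-9
  g <- 2.5
  dev <- one_cell_device(tau = tau, gain = g)

  # one photon on a never-fired (fully charged) cell releases the full gain
  arr1 <- photon_arrivals(1e-6, 1L, 2e-6)
  tr1 <- simulate_response(arr1, dev, 125e6)
  expect_identical(sum(tr1$samples), g)

  # two photons separated by dt: second releases g * (1 - exp(-dt/tau))
  for (dt in c(5e-9, 20e-9, 100e-9)) {
    arr2 <- photon_arrivals(c(0, dt), c(1L, 1L), 1e-6)
    tr2 <- simulate_response(arr2, dev, 125e6)
    expect_equal(sum(tr2$samples), g * (1 + (1 - exp(-dt / tau))))
  }

  # periodic arrivals, period T: every photon after the first releases
  # exactly g * (1 - exp(-T/tau)) (machine precision)
  T <- 13e-9
  arr <- periodic_arrivals(200, T)
  tr <- simulate_response(arr, dev, 125e6)
  expect_equal(sum(tr$samples), g * (1 + 199 * (1 - exp(-T / tau))),
               tolerance = 1e-12)
})

test_that("response traces conserve charge and are seed-deterministic", {
  dev <- small_device(n = 20, tau = 50e-9)
  arr <- simulate_arrivals(5e8, 1e-5, dev, seed = 42)
  tr <- simulate_response(arr, dev, 125e6)
  n_det <- length(arr$times)
  expect_lte(sum(tr$samples), n_det * dev$single_cell_gain + 1e-9)
  expect_gt(sum(tr$samples), 0)

  tr2 <- simulate_response(simulate_arrivals(5e8, 1e-5, dev, seed = 42),
                           dev, 125e6)
  expect_identical(tr$samples, tr2$samples)

  bad <- photon_arrivals(1e-6, 99L, 1e-5)
  expect_error(simulate_response(bad, dev), "out of range")
})

test_that("low-flux mean trace amplitude matches the linear expectation", {
  dev <- small_device(n = 1000, tau = 20e-9, pde = 0.5, gain = 3)
  flux <- 1e8   # per-cell occupancy << 1
  arr <- simulate_arrivals(flux, 2e-3, dev, seed = 5)
  tr <- trim_settling(simulate_response(arr, dev, 125e6), dev)
  expected <- flux * dev$pde * dev$single_cell_gain / 125e6
  expect_equal(mean(tr$samples), expected, tolerance = 5e-3)
})

test_that("trim_settling removes the stated window and the start-up bias", {
  dev <- small_device(n = 100, tau = 20e-9)
  # arithmetic: 50 tau at 125 MHz = 1 us = 125 samples
  tr <- sampled_trace(rnorm(1000) + 10, 125e6)
  trimmed <- trim_settling(tr, dev, 50)
  expect_length(trimmed$samples, 1000 - 125)
  expect_equal(trimmed$discard_prefix, 1e-6)
  expect_identical(trim_settling(tr, dev, 0), tr)
  expect_error(trim_settling(sampled_trace(rnorm(100), 125e6), dev, 50),
               "settling window")

  # settling oracle: cells start fully charged, so the untrimmed mean under
  # a step of strong illumination exceeds the recharge-equilibrium steady
  # state; after trimming the mean matches the analytic value
  # n_cells * lambda_cell * g / (1 + lambda_cell * tau) / fs.
  flux <- 5e10   # per-cell rate 5e8 -> a = lambda*tau = 10, heavy pile-up
  arr <- simulate_arrivals(flux, 4e-5, dev, seed = 9)
  raw <- simulate_response(arr, dev, 125e6)
  trm <- trim_settling(raw, dev, 50)
  lam_c <- flux / dev$n_microcells
  steady <- dev$n_microcells * lam_c /
    (1 + lam_c * dev$recharge_time_constant) / 125e6
  expect_equal(mean(trm$samples), steady, tolerance = 0.01)
  expect_gt(mean(raw$samples), mean(trm$samples))
})

test_that("detected fraction falls with flux and matches the 1-cell renewal oracle", {
  # single cell, Poisson arrivals rate lambda: mean released fraction per
  # photon is 1/(1 + lambda * tau) in equilibrium
  tau <- 20e-9
  dev1 <- one_cell_device(tau = tau)
  lam <- 5e7   # a = 1
  dfc1 <- detected_fraction_curve(dev1, lam, duration = 2e-2, seeds = 1:3)
  expect_equal(dfc1$detected_fraction, 1 / (1 + lam * tau), tolerance = 0.01)
  expect_lt(dfc1$detected_fraction, 0.6)   # substantially below 1

  # low-flux limit -> 1
  dev <- small_device(n = 200, tau = tau)
  dfc0 <- detected_fraction_curve(dev, 1e6, duration = 2e-2, seeds = 1)
  expect_equal(dfc0$detected_fraction, 1, tolerance = 5e-3)

  # monotone nonincreasing across an ascending grid (3x MC standard error)
  grid <- 10^seq(8, 10.5, length.out = 6)
  dfc <- detected_fraction_curve(dev, grid, duration = 1e-4, seeds = 1:2)
  slack <- 3 * ifelse(is.na(dfc$se), 0, dfc$se)
  expect_true(all(diff(dfc$detected_fraction) <=
                    (slack[-1] + slack[-length(slack)])))
})
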