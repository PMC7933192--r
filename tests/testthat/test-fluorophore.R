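# Pulsed-excitation steady state, repetition-rate sweeps, two-photon
# saturation, pulse-energy bookkeeping.

test_that("closed-form steady state matches brute-force pulse stepping", {
  cases <- rbind(
    expand.grid(conv = c("per_pulse", "post_pulse"),
                tau = c(0.5e-9, 3e-9, 10e-9), rate = c(78e6, 312e6),
                stringsAsFactors = FALSE),
    # the time-averaged constraint is only satisfiable when the excited
    # state survives a meaningful fraction of the pulse period
    expand.grid(conv = "time_averaged", tau = c(3e-9, 10e-9), rate = 312e6,
                stringsAsFactors = FALSE)
  )
  for (j in seq_len(nrow(cases))) {
    fl <- fluorophore_params(cases$tau[j], cases$conv[j])
    rate <- cases$rate[j]
    ss <- excitation_steady_state(rate, fl)
    # step the recursion x' = x e + p (1 - x e) for 1e4 pulses
    e <- exp(-1 / (rate * cases$tau[j]))
    x <- 0
    for (i in 1:1e4) x <- x * e + ss$p * (1 - x * e)
    expect_equal(ss$x_post, x, tolerance = 1e-6)
    expect_equal(ss$yield_per_s, rate * x * (1 - e), tolerance = 1e-6)
  }
})

test_that("steady state obeys its limiting regimes", {
  # T >> tau: every pulse finds a relaxed population; per-pulse convention
  # gives x -> target and yield -> target * rate
  fl <- fluorophore_params(1e-12, "per_pulse", 0.1)
  ss <- excitation_steady_state(78e6, fl)
  expect_equal(ss$x_post, 0.1, tolerance = 1e-12)
  expect_equal(ss$yield_per_s, 0.1 * 78e6, tolerance = 1e-12)

  # tau -> infinity with finite p: population accumulates toward 1 and the
  # yield per pulse vanishes
  fl2 <- fluorophore_params(1, "per_pulse", 0.1)
  ss2 <- excitation_steady_state(78e6, fl2)
  expect_gt(ss2$x_post, 0.999)
  expect_lt(ss2$yield_per_s / 78e6, 1e-6)

  # time-averaged convention: yield/s = target/tau independent of rate
  # (closed form) - this convention cannot produce any rate dependence
  fl3 <- fluorophore_params(10e-9, "time_averaged", 0.1)
  yields <- vapply(c(78e6, 156e6, 312e6), function(r) {
    excitation_steady_state(r, fl3)$yield_per_s
  }, numeric(1))
  expect_equal(yields, rep(0.1 / 10e-9, 3), tolerance = 1e-12)

  # unsatisfiable time-averaged constraint errors out
  fl4 <- fluorophore_params(2e-9, "time_averaged", 0.5)
  expect_error(excitation_steady_state(1e6, fl4), "unsatisfiable")
})

test_that("repetition sweep is normalized at the reference and sublinear in rate", {
  rates <- c(19.5e6, 39e6, 78e6, 156e6, 312e6)
  fl <- fluorophore_params(3e-9, "post_pulse", 0.1)
  sw <- repetition_sweep(rates, fl)
  ref <- sw[sw$rate_hz == 78e6, ]
  expect_equal(ref$relative_yield, 1)
  expect_equal(ref$relative_power, 1)

  # sublinearity: yield per unit rate declines monotonically with rate
  expect_true(all(diff(sw$relative_yield / (rates / 78e6)) <= 1e-9))
  # and above the reference, relative yield trails relative rate
  hi <- rates > 78e6
  expect_true(all(sw$relative_yield[hi] <= rates[hi] / 78e6 + 1e-9))

  # vanishing lifetime: yield and power both track the rate linearly
  sw0 <- repetition_sweep(rates, fluorophore_params(1e-13, "post_pulse", 0.1))
  expect_equal(sw0$relative_yield, rates / 78e6, tolerance = 1e-6)
  expect_equal(sw0$relative_power, rates / 78e6, tolerance = 1e-6)

  # at 4x the rate the yield gain is <= 4 and shrinks with lifetime
  gain4 <- vapply(c(0.5e-9, 3e-9, 10e-9), function(tau) {
    s <- repetition_sweep(312e6, fluorophore_params(tau, "post_pulse", 0.1))
    s$relative_yield
  }, numeric(1))
  expect_true(all(gain4 <= 4))
  expect_true(all(diff(gain4) < 0))
})

test_that("two-photon law and saturation onset follow the algebra", {
  expect_equal(twophoton_signal(2, 3), 12)
  expect_equal(twophoton_signal(0, 3), 0)
  # doubling power quadruples the unsaturated signal
  expect_equal(twophoton_signal(4, 1) / twophoton_signal(2, 1), 4)
  expect_error(twophoton_signal(-1), "power")

  # synthetic saturating data c P^2 / (1 + P^2/Ps^2): 10% deviation at Ps/3
  # (log-spaced grid so the low-power anchor region is truly unsaturated)
  P <- exp(seq(log(0.3), log(40), length.out = 200))
  Ps <- 30
  sig <- 2 * P^2 / (1 + P^2 / Ps^2)
  res <- twophoton_saturation_power(P, sig)
  expect_true(res$crossed)
  expect_equal(res$saturation_power, Ps / 3, tolerance = 0.02)

  expect_error(twophoton_saturation_power(c(1, 2), c(1, 4)), "3 grid points")
})

test_that("pulse energy is average power over repetition rate", {
  expect_equal(round(pulse_energy(76.1e-3, 78e6) * 1e9, 2), 0.98)
  expect_equal(round(pulse_energy(36.4e-3, 78e6) * 1e9, 2), 0.47)
  expect_identical(pulse_energy(0, 78e6), 0)
  expect_error(pulse_energy(1, 0), "rep_rate")
})
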