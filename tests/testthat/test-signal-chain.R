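# Two-exponential impulse response, pole-zero cancellation, filtering,
# equivalent bandwidth, clipping and bias droop.

test_that("impulse response kernel carries the configured charge split", {
  fs <- 1e10
  p <- impulse_response_params(1e-9, 40e-9, 10)
  k <- impulse_response(p, fs, single_cell_gain = 2)
  t <- seq_along(k$samples - 1)
  tt <- (seq_along(k$samples) - 1) / fs

  # total integral = gain (trapezoid vs closed form)
  expect_equal(pracma::trapz(tt, k$samples), 2, tolerance = 1e-3)

  # slow component holds 10/11 of the charge
  A_f <- 2 / (11 * 1e-9)
  slow <- k$samples - A_f * exp(-tt / 1e-9)
  expect_equal(pracma::trapz(tt, slow), 2 * 10 / 11, tolerance = 1e-3)

  # ratio = 0 is a pure fast exponential
  k0 <- impulse_response(impulse_response_params(1e-9, 40e-9, 0), fs)
  expect_equal(k0$samples, k0$samples[1] * exp(-tt / 1e-9), tolerance = 1e-12)

  # unresolved fast constant warns
  expect_warning(impulse_response(p, 125e6), "aliased")
})

test_that("matched pole-zero cancellation removes the slow component", {
  fs <- 1e10
  tau_s <- 40e-9
  g <- 1
  k <- impulse_response(impulse_response_params(1e-9, tau_s, 10), fs,
                        single_cell_gain = g)
  y <- apply_pzc(k, tau_s)   # attenuation 1/11

  # transmitted charge = fast-component charge = g/11 (DC gain = 1/11);
  # plain sums because the output is pulse-like at the first sample
  tt <- (seq_along(y$samples) - 1) / fs
  expect_equal(sum(y$samples) / fs, g / 11, tolerance = 0.02)

  # the tau_s exponential is annihilated: tail energy (beyond the fast pulse
  # and the collapsed pole transient) under 1% of the input slow energy
  A_s <- g * 10 / (11 * tau_s)
  slow_energy <- A_s^2 * tau_s / 2
  tail <- y$samples[tt > 30e-9]
  expect_lt(sum(tail^2) / fs / slow_energy, 0.01)
})

test_that("mismatched PZC leaves the partial-fraction slow residual", {
  fs <- 1e10
  tau_s <- 40e-9
  A <- 3
  n <- 4000
  x <- A * exp(-(0:(n - 1)) / (fs * tau_s))
  tau_z <- 0.8 * tau_s
  atten <- 1 / 11
  y <- apply_pzc(x, tau_z, attenuation = atten, sample_rate = fs)
  r <- exp(-1 / (fs * tau_s))
  q <- exp(-1 / (fs * tau_z))
  p <- exp(-1 / (fs * atten * tau_z))
  C1 <- A * (r - q) / (r - p)   # residual slow amplitude
  idx <- 2000   # pole transient long gone
  expect_equal(y[idx] / r^(idx - 1), C1, tolerance = 1e-9)

  # an exponential slower than the collapsed pole keeps its decay shape
  # once the pole transient (tau_s/11 = 3.6 ns here) has died away
  tau_f <- 6e-9
  xf <- exp(-(0:(n - 1)) / (fs * tau_f))
  yf <- apply_pzc(xf, tau_s, sample_rate = fs)
  i <- 700:1000
  expect_equal(yf[i + 1] / yf[i], rep(exp(-1 / (fs * tau_f)), length(i)),
               tolerance = 1e-3)
})

test_that("lowpass filtering obeys unity DC gain and Parseval", {
  fs <- 125e6
  # DC input -> unchanged level once settled
  const <- apply_lowpass(rep(4, 5000), 25e6, sample_rate = fs)
  expect_equal(mean(const[1000:5000]), 4, tolerance = 1e-9)

  # white noise variance shrinks by the filter's equivalent bandwidth
  set.seed(1)
  x <- rnorm(1e6)
  y <- apply_lowpass(x, 25e6, sample_rate = fs)
  eb <- equivalent_bandwidth(lowpass_transfer_function(25e6, 4, fs), fs)
  expect_equal(var(y) / var(x), eb, tolerance = 0.02)

  # cutoff near Nyquist is near-identity
  sm <- sin(2 * pi * 1e6 * (0:4999) / fs)
  y2 <- apply_lowpass(sm, fs / 2 * 0.999, sample_rate = fs)
  expect_equal(y2[500:5000], sm[500:5000], tolerance = 1e-3)

  expect_error(apply_lowpass(x, 80e6, sample_rate = fs), "Nyquist")
})

test_that("equivalent bandwidth matches closed forms and stays in (0, 1]", {
  fs <- 125e6
  # ideal 25 MHz brick-wall against the 62.5 MHz Nyquist reference
  expect_equal(equivalent_bandwidth(brickwall_transfer_function(25e6, 62.5e6),
                                    fs), 0.4, tolerance = 1e-6)
  # all-pass
  ap <- transfer_function(c(0, 62.5e6), c(1, 1))
  expect_equal(equivalent_bandwidth(ap, fs), 1)
  # single pole: fc * atan(fN/fc) / fN
  fc <- 20e6
  fN <- fs / 2
  sp <- single_pole_transfer_function(fc, fN, n_points = 2e5)
  expect_equal(equivalent_bandwidth(sp, fs), fc * atan(fN / fc) / fN,
               tolerance = 1e-4)
  # grid must reach Nyquist
  expect_error(equivalent_bandwidth(brickwall_transfer_function(1e6, 10e6),
                                    fs), "cover")
  # normalized lowpass responses stay in (0, 1]
  for (ord in c(1, 2, 4, 8)) {
    eb <- equivalent_bandwidth(lowpass_transfer_function(10e6, ord, fs), fs)
    expect_gt(eb, 0)
    expect_lte(eb, 1)
  }
})

test_that("amplifier clipping clamps to the rails and reports the fraction", {
  x <- c(-2, 0, 1, 5)
  y <- clip_amplifier(x, -Inf, Inf)
  expect_equal(as.numeric(y), x)
  expect_equal(attr(y, "clipping_fraction"), 0)

  y2 <- clip_amplifier(x + 100, 0, 10)
  expect_equal(as.numeric(y2), rep(10, 4))
  expect_equal(attr(y2, "clipping_fraction"), 1)

  y3 <- clip_amplifier(x, 0, 10, dc_offset = 2)
  expect_equal(as.numeric(y3), c(0, 2, 3, 7))
  expect_error(clip_amplifier(x, 5, 1), "rail_low")
})

test_that("current-domain PZC clips at roughly 11x higher flux than voltage-domain", {
  # identical rails; the voltage-domain chain amplifies the full 11-unit
  # charge per photon while the current-domain chain sees only the fast
  # 1-unit share, so clipping onset moves by about the 10:1 charge ratio.
  fs <- 1e10
  tau_s <- 40e-9
  k_full <- impulse_response(impulse_response_params(1e-9, tau_s, 10), fs)
  k_pzc <- apply_pzc(k_full, tau_s)
  rail <- 5e8   # well above a single pulse peak: the mean level clips first
  onset <- function(kernel) {
    rates <- 10^seq(6.5, 10.5, length.out = 41)
    frac <- vapply(rates, function(rate) {
      step <- max(1L, round(fs / rate))
      train <- rep(0, 20000)
      train[seq(1, 20000, by = step)] <- 1
      y <- stats::convolve(train, rev(kernel$samples), type = "open")
      y <- y[5000:20000]   # settled region
      attr(clip_amplifier(y, -Inf, rail), "clipping_fraction")
    }, numeric(1))
    rates[which(frac > 0.5)[1]]
  }
  ratio <- onset(k_pzc) / onset(k_full)
  expect_gt(ratio, 8)
  expect_lt(ratio, 14)
})

test_that("bias droop is a soft knee, flat up to the current limit", {
  sup <- bias_supply(max_current = 10e-3)
  expect_equal(bias_droop(0, sup), 1)
  expect_equal(bias_droop(10e-3, sup), 1)   # knee onset
  sweep <- bias_droop(seq(0, 0.1, length.out = 100), sup)
  expect_true(all(diff(sweep) <= 0))
  expect_lt(bias_droop(50e-3, sup), 1)
  expect_error(bias_droop(-1e-3, sup), "mean_current")
})
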