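# Small test devices and shared helpers.

# one microcell, ideal detection: closed-form oracles are computable
one_cell_device <- function(tau = 20e-9, gain = 1) {
  sipm_device(n_microcells = 1, recharge_time_constant = tau,
              pde = 1, single_cell_gain = gain)
}

small_device <- function(n = 100, tau = 20e-9, pde = 1, gain = 1, ...) {
  sipm_device(n_microcells = n, recharge_time_constant = tau, pde = pde,
              single_cell_gain = gain, ...)
}

# deterministic periodic arrivals on a single cell
periodic_arrivals <- function(n_events, period, duration = NULL) {
  times <- (seq_len(n_events) - 1) * period
  duration <- duration %||% (times[n_events] + period)
  photon_arrivals(times, rep(1L, n_events), duration)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
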