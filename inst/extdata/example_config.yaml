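# Example run configuration for sipmsim.
# All physical quantities carry unit suffixes in their key names
# (_hz, _s, _w, _a, _v, _ohm, _f, _pps = photons/s, _dn).
# Device values are datasheet-derived representative numbers for a
# 3 mm / 25 um-pitch SiPM (S14420-3025 class); gain and dark noise follow
# a digitized chain reading 12.9 DN/photon with a 5.97 DN dark frame.
seed: 1
sample_rate_hz: 1.25e+8
device:
  n_microcells: 14400
  quench_resistance_ohm: 1.5e+5
  junction_capacitance_f: 1.5e-13     # tau_rc = 22.5 ns
  pde: 0.4
  single_cell_gain_dn: 12.9
  overvoltage_v: 7.0
  dark_count_rate_hz: 0.0
  dark_sd_dn: 5.97
chain:
  fast_time_constant_s: 2.0e-9
  slow_time_constant_s: 2.25e-8       # matches the cell recharge pole
  slow_to_fast_charge_ratio: 10.0
  pzc_time_constant_s: 2.25e-8
  pzc_attenuation: 9.0909e-2          # 1/11: diverts the 10:1 slow charge
  lowpass_cutoff_hz: 2.5e+7
  lowpass_order: 4
  bias:
    max_current_a: 1.0e-2
    bias_voltage_v: 50.0
    droop_sharpness: 1.0
scan:
  line_rate_hz: 2.4e+4
  pixels_per_line: 2048
  lines_per_frame: 2048
  fill_fraction: 1.0
fluorophore:
  lifetime_s: [5.0e-10, 3.0e-9, 1.0e-8]
  excitation_constraint: post_pulse
  target_fraction: 0.1
laser:
  repetition_rate_hz: 7.8e+7
  average_power_w: 7.61e-2
pmt:
  excess_noise_factor: 1.5
  saturation_flux_pps: 3.0e+9
  quantum_efficiency: 0.4
ptc:
  flux_min_pps: 1.0e+8
  flux_max_pps: 1.0e+10
  n_flux: 5
  min_samples: 1.0e+6
  max_samples: 2.0e+7
  target_events: 4.0e+6
  trim_constants: 50
sipm_linearity_flux_pps: 4.0e+10
sweep:
  rate_min_hz: 1.0e+7
  rate_max_hz: 1.0e+9
  n_rates: 25
  reference_rate_hz: 7.8e+7
frames:
  size_px: 64
  photons_per_pixel: 100.0
  n_frames: 16
  detector: ideal
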