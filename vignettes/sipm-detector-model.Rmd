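---
title: "Modeling SiPM detectors for high-speed two-photon microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling SiPM detectors for high-speed two-photon microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipmsim)
```

# The problem

Point-scanning fluorescence microscopes trade speed against signal-to-noise:
at a pixel rate $p$, a detector that cannot accept more than $\Phi_{sat}$
photons/s caps the photons per pixel at $\Phi_{sat}/p$, and with pure shot
noise the per-pixel SNR at $\sqrt{\Phi_{sat}/p}$. Photomultiplier tubes add
multiplication (excess) noise and saturate early; silicon photomultipliers
(SiPMs) saturate orders of magnitude later but are arrays of discrete
Geiger-mode microcells whose recharge dynamics shape both the linearity and
the spectrum of the output. `sipmsim` models this chain end to end so that
detector and scan parameters can be explored quantitatively before anything
is built.

# The Monte Carlo microcell model

Photons are launched as a homogeneous Poisson process at flux $\Phi$
(photons/s), thinned by the photon detection efficiency (PDE), and each
surviving photon is assigned to one of $N$ microcells — uniformly by
default, or with a user-supplied illumination profile to represent uneven
light distribution on the sensor, which increases nonlinearity because hot
cells saturate first. Thinning is applied *before* cell assignment; since
assignment is independent of detection this ordering is statistically
equivalent to thinning afterwards and cheaper.

Each cell carries a charge state $c \in [0, 1]$ recovering as
$1 - e^{-\Delta t/\tau_{rc}}$ since its last avalanche, with
$\tau_{rc} = R_q C_j$. A photon striking a cell at state $c$ releases charge
$c \cdot g$ ($g$ = single-cell gain) and resets the state to 0: a Geiger
discharge empties the cell even when only partially recharged, so the
recharge clock restarts on every avalanche. This choice makes the per-event
charge depend only on the time since the previous event on the same cell,
which is why the event loop reduces to an exact grouped vectorized
computation. Released charge is accumulated wholly into the sample bin
containing the arrival time (125 MHz default), keeping charge conservation
exact; sub-sample interpolation would buy nothing at the bandwidths
involved.

Cells start fully charged — an idle detector — so a step of strong
illumination begins with a transient of *elevated* output that relaxes to
the recharge equilibrium; `trim_settling()` discards the first 50
$\tau_{rc}$ by default before any statistics are computed.

Dark counts are available as an optional extra Poisson process (default rate
0); optical crosstalk and afterpulsing are deliberately not modeled — they
perturb the effective gain distribution rather than the pile-up physics this
package is about.

## Device defaults

The worked device profile `sipm_device_s14420()` describes a 3 mm,
25 µm-pitch sensor: 14400 microcells, $R_q = 150\,\mathrm{k\Omega}$,
$C_j = 0.15\,\mathrm{pF}$ (so $\tau_{rc} = 22.5$ ns), PDE 0.4. These are
datasheet-derived representative values. The gain (12.9 DN/photon) and
dark-frame standard deviation (5.97 DN) are measured values for a digitized
amplifier chain operated 7 V above breakdown, carried as profile defaults.

## Closed-form anchors

Two oracles pin the implementation:

* a single cell receiving deterministic periodic arrivals of period $T$
  releases exactly $g(1 - e^{-T/\tau_{rc}})$ per photon after the first
  (machine precision);
* a single cell under Poisson arrivals at rate $\lambda$ releases, in
  equilibrium, a mean fraction $1/(1 + \lambda\tau_{rc})$ of the full
  charge — the renewal-process yield, since exponential inter-arrival times
  give $E[1 - e^{-\Delta t/\tau}] = 1/(1+\lambda\tau)$.

# Photon-transfer-curve analysis

For a shot-noise-limited analog output, Poisson statistics tie the sample
mean and variance together. With the analog bandwidth folded in through the
*equivalent bandwidth* — the integrated power of the chain's $|H(f)|^2$
divided by that of a unit brick-wall at Nyquist — the absolute detected flux
is

$$\mathrm{photons/s} = \frac{\mathrm{mean}^2}{\mathrm{variance}}
  \times \mathrm{EB} \times f_s .$$

The estimate is exactly invariant to positive rescaling of the trace, uses
the unbiased $(n-1)$ variance, and refuses constant traces (zero variance
carries no information). An unfiltered binned Monte Carlo trace is white up
to Nyquist, so EB = 1 there; after the 4th-order 25 MHz Butterworth (the
default anti-alias choice, config-selectable) EB evaluates to ≈ 0.42,
close to the 25/62.5 = 0.4 of an ideal brick-wall. Equivalent-bandwidth
integration is trapezoidal on the caller's grid; grid density is the
caller's responsibility (the provided constructors use 4096 points, and the
brick-wall grid places points on both sides of the edge so the integral is
exact to ~10⁻⁹).

The estimator counts photons at the detector plane; `simulate_ptc()`
divides by the PDE when comparing against launched flux. Gain is recovered
from the least-squares slope of variance against mean across an
illumination sweep (free intercept absorbing dark/read noise), divided by
EB.

Linearity-deviation curves fit a through-origin reference slope over the
lowest decade of the flux grid (the paper-style plots need *some* linear
anchor; the lowest decade is configurable), and the 10% crossing is
interpolated linearly in log-flux because the deviation curves are smooth
in the log domain.

One regime deserves a warning: in *deep* pile-up (per-cell arrival interval
well below $\tau_{rc}$, deviation beyond tens of percent) the released
charges become negatively correlated between nearby samples, the variance
collapses, and the mean²/variance estimator turns back *upward* — the
deviation-from-linear curve is monotone only up to moderate saturation
(roughly $\lambda_{cell}\tau_{rc} \lesssim 1$). All quantitative claims in
the tests and acceptance sweep stay below that regime, as do the operating
points of practical interest.

# The signal chain

The single-photon response is modeled as
$A_f e^{-t/\tau_f} + A_s e^{-t/\tau_s}$ with the integrated charge split
$A_s\tau_s : A_f\tau_f$ = 10 : 1 by default: a sub-nanosecond fast spike
from the array capacitance and a slow tail at the cell-recharge time
constant carrying ten times the charge.

Pole-zero cancellation places a zero at the recharge pole $1/\tau_{pzc}$
and a pole at $1/(a\,\tau_{pzc})$, $a$ = `attenuation`. Two properties
matter:

* the DC gain of any realizable pole-zero stage equals $a$, so the
  transmitted charge is $a$ times the input charge. The default
  $a = 1/11$ diverts exactly the slow share of the 10 : 1 split, so the
  charge reaching the amplifier equals the fast-component charge — this is
  what extends the amplifier dynamic range by the ~11× charge ratio, and it
  is why the current-domain (PZC-first) chain clips at roughly 11× higher
  flux than a voltage-domain chain with identical rails;
* discretization uses the matched-z mapping ($z = e^{sT}$) rather than the
  bilinear transform: a sampled exponential with a matched time constant is
  annihilated *exactly* by the discrete zero, which makes the cancellation
  testable to machine precision instead of up to warping error.

Lowpass filtering is a causal 4th-order Butterworth (order and cutoff
configurable); white noise passed through it loses variance by exactly the
filter's equivalent bandwidth (Parseval), which the tests verify at the 2%
level on 10⁶-sample traces. Amplifier clipping shifts by a DC offset and
clamps to rails, reporting the clipped fraction. Bias-supply droop is an
optional soft knee — scale 1 up to the current limit (10 mA default),
declining as $1/(1 + k(I/I_{max} - 1))$ beyond it; it is a phenomenological
stand-in for a current-limited boost converter, not a converter model.

The measured 60 MHz 3 dB analog bandwidth of the physical amplifier is
treated as an anecdote, not a model target: the feedback component values
that set it are not part of the model.

# Fluorophore kinetics under pulsed excitation

Between pulses of a train at rate $R$ (period $T = 1/R$) an excited
population relaxes by $e^{-T/\tau}$; each pulse excites a fraction $p$ of
the ground-state molecules it finds. The post-pulse excited fraction obeys
$x' = x e^{-T/\tau} + p(1 - x e^{-T/\tau})$, a linear recursion whose fixed
point $x^\ast = p / (1 - e^{-T/\tau}(1-p))$ is solved in closed form (the
recursion is linear, so iteration would add nothing; a 10⁴-pulse
time-stepping oracle confirms the fixed point to better than 10⁻⁶).
Fluorescent yield per fluorophore per second is $R\,x^\ast(1 - e^{-T/\tau})$
at unit quantum yield.

"Exciting 10% of fluorophores" is ambiguous for a pulse train, so three
conventions are implemented: fixed per-pulse excitation fraction, fixed
post-pulse excited fraction (the default — it best matches the intended
"keep 10% excited in steady state" reading), and fixed time-averaged
excited fraction. The last is included largely as documentation: it forces
yield/s $= \mathrm{target}/\tau$ *independent of repetition rate* (closed
form), so it cannot produce any rate dependence of fluorescence — evidence
that it is not what rate-dependence plots mean. It is also only satisfiable
when the excited state survives a meaningful fraction of the period.

For power bookkeeping the two-photon law at fixed pulse width is used:
per-pulse excitation probability $\propto E^2$, so pulse energy
$\propto \sqrt{p}$ and average power $= R\,E$. Sweeps are normalized to a
78 MHz reference. Saturation onset on a measured power sweep is flagged
where the signal drops more than 10% below an intensity-squared law
anchored on the low-power points.

# Imaging SNR accounting

A bidirectional resonant scanner sweeps sinusoidally; with fill fraction
$f$ (the digitized share of the sweep amplitude), the peak-to-average pixel
rate ratio is $\arcsin(f)/f$, rising to $\pi/2$ for the full sweep. The
average rate is line rate × pixels per line (24,000 × 2048 ≈ 49.2 MP/s for
the default geometry). Measured systems report ratios slightly below
$\pi/2$; `fill_fraction` is exposed precisely so a measured geometry can be
matched rather than reverse-engineered.

Per-pixel SNR over a frame stack is mean/sd across frames. Synthetic stacks
are Poisson in photon counts; the PMT tag inflates the noise variance by
the excess noise factor $F$ (SNR $= \sqrt{n/F}$; $F$ has no default because
it depends on tube and gain) and clips at the tube's saturation; the SiPM
tag applies a mean-field pile-up transform calibrated by running the Monte
Carlo's detected-fraction curve at the pixel dwell time. The mean-field
transform reproduces the compression of bright pixels but not the
sub-Poisson variance of deep pile-up — a documented simplification.

# What the generator does and does not emulate

The Monte Carlo is the package's synthetic-data source. It reproduces
Poisson arrival statistics, PDE thinning, per-cell RC recharge, pile-up
compression, illumination inhomogeneity and (optionally) dark counts, at
the experimental 125 MHz sampling. It does not include optical crosstalk,
afterpulsing, gain drift with temperature, amplifier noise, or the pulsed
(square-wave) excitation protocol used with real LEDs — each flux point is
simulated under steady illumination, with the settling window discarded, so
passing tests demonstrate correctness of the shot-noise/pile-up physics,
not immunity to those effects in real hardware.

# Problem sizes and numerical choices

The acceptance sweep uses the 14400-cell profile over 10⁸–10¹⁰ photons/s
(5 log-spaced points), ≥10⁶ samples per point and a target of ~4×10⁶
detected events at the low-flux end, which keeps the per-point estimator
error near 0.1% and the whole sweep around two minutes on one CPU. Unit
tests use smaller devices (1–2000 cells) where the closed-form oracles are
sharp. All simulations run from a single seeded generator; derived
per-point seeds are drawn once from the master seed, and outputs record the
seed used.

# Known limitations

* No SPICE-level circuit modeling, PCB parasitics, or amplifier noise
  figure; the chain is behavioral.
* The flux estimator inverts in deep pile-up (above, roughly, the 30–50%
  deviation region); linearity claims are restricted to moderate
  saturation.
* Fluorophore kinetics are single-exponential with no triplet states or
  photobleaching.
* The bias-droop knee is phenomenological; coefficients should be fit to a
  measured supply if quantitative droop matters.
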