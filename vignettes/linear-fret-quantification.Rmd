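---
title: "Linear quantification of FRET probe measurements: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear quantification of FRET probe measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretlin)
```

## The problem

A unimolecular FRET biosensor carries a donor and an acceptor fluorophore
around a sensing unit; a biochemical activity switches the probe between a
FRET-poor inactive conformation and a FRET-rich active one. Two questions
decide whether such data are usable for quantitative modeling: *what model
variable* does the signal track, and *is the measurement linear* in the
fraction of FRET-competent probes, `phi_F`? `fretlin` implements the
forward models that answer both, the estimators that exploit linearity
where it exists, and synthetic-data generators that let every claim be
tested end to end.

## Probe activation kinetics

The active-probe concentration `P*` results from a covalent-modification
cycle driven by a forward enzyme (maximal activity `F_a`,
concentration/time) and a reverse enzyme (`R_a`), with Michaelis constants
`K_MF`, `K_MR` (concentration) and total probe `P_TOT`. We treat the
activities as Vmax-type maximal rates; this is the unit reading under which
the saturated-forward balance `F_a = R_a P*/K_MR` is dimensionally
consistent. Three closed-form limits are implemented
(`steady_state_limit()`):

* forward saturated, reverse linear: `P* = F_a K_MR / R_a` — the only
  regime in which `P*` is linear in `F_a`;
* reverse saturated, forward linear: `P* = P_TOT - R_a K_MF / F_a`;
* both linear: `P* = P_TOT (F_a/K_MF) / (F_a/K_MF + R_a/K_MR)`.

The full Michaelis–Menten balance (`steady_state_mm()`) is the
Goldbeter–Koshland steady state, a quadratic in `P*` with exactly one root
in `[0, P_TOT]` for positive activities. Numerical choices: the quadratic
is solved with the numerically stable q-formula; if floating-point noise
places both roots inside the interval, the root with the smaller absolute
rate imbalance wins. A closed-form limit that lands outside `[0, P_TOT]`
raises a regime-inconsistency error rather than being clipped, since it
means the stated limit assumptions cannot hold. Two independent oracles —
bisection of the rate balance and `deSolve::lsoda` time integration from
`P*(0) = 0` — cross-check the algebra in the tests. The ODE oracle stops
when the residual net rate falls below `tol` times the dominant activity;
because that is a rate criterion, its `P*` accuracy degrades where the rate
curve is flat, so tests run it at `tol = 1e-10` and compare at `1e-6` of
`P_TOT` while bisection is compared at `1e-8`. `linearity_deviation()`
quantifies departure from linearity as the maximum OLS residual of
`P*(F_a)` over a grid, relative to the response range; it requires at least
three distinct activities because an affine fit through two points is exact
by construction. Steady state is itself an idealization — intracellular
reactions are rarely at steady state — so these maps are best used to
decide *what to compare FRET data to* (a modeled substrate, not an enzyme
activity), not to fit time courses.

## Spectra, bands and coverage coefficients

Channel intensities are linear in the number of emitting molecules with
coefficients `f_DD`, `f_AD`, `f_AA` (and optionally `f_DA`), each a quantum
yield times the fraction of the normalized emission density falling in the
channel band. Bands are closed intervals; the plate protocol's native
dialect is a 5 nm sample grid with channels defined as inclusive band sums
(donor 480–500 nm, acceptor 525–565 nm, nominal FRET channel 515–565 nm;
emission scans 480–565 nm under 436 nm excitation and 525–565 nm under
505 nm excitation). Two conventions are therefore exposed:
`coverage_fraction()` integrates by the trapezoid rule (the physical
photons-per-molecule reading), while `coverage_sum()` uses plain 5 nm band
sums — the quantity an instrument that reports per-wavelength intensities
actually sums. The simulator and its round-trip tests use the sum
convention so channel sums of a noise-free simulated plate reproduce the
closed-form ratios exactly; the two conventions agree up to a
band-independent scale and never change a ratio's shape in `phi_F`.

Real donor/acceptor spectra are not tabulated here; `default_spectra()`
supplies log-normal stand-ins peaking at 492 nm (donor, quantum yield 0.85)
and 528 nm (acceptor, 0.57) — literature-typical values for a teal/yellow
fluorescent-protein pair — with a red-tail shape parameter (`skew = 0.35`,
Gaussian-limit width 14 nm). Only ratios of band integrals enter any model,
so the stand-ins' role is to provide realistic relative crosstalk, not
absolute photometry. Trapezoid coverage on the default 1 nm grid converges
under refinement at second order; for the narrow (14 nm) FP-like spectra
the 1 nm-vs-0.1 nm difference is about `3e-4`, dropping below `1e-4` for
widths of 30 nm and above — a property of curvature, documented rather than
hidden. The overlap-index series reproduces the variable-overlap
construction (FRET-channel lower edge stepped from 535 down to 480 nm, 12
bands); the index is normalized as the donor's FRET-band coverage over its
donor-channel coverage, one admissible scaling of a quantity defined only
up to proportionality with `f_AD/f_DD`.

## Ratiometric models

With `x = E * phi_F` the apparent FRETing fraction, donor excitation gives
`I_D^don = gain_D N_D* (1 - x) f_DD` (acceptor bleed-in `f_DA` defaults to
0, as it is ordinarily easy to exclude acceptor emission from the donor
channel) and `I_A^don = gain_A [ (N_D* x + N_A^direct) f_AA +
N_D* (1 - x) f_AD ]`. Direct acceptor excitation at the donor wavelength
defaults to zero, and the separate acceptor-excitation exposure sees only
acceptors: `I_A^acc = gain_A N_A^acc f_AA`. Detector gains enter as
per-channel multipliers, deliberately separated from the spectral physics:
they are instrument settings. Consequences, each of which is a tested
property:

* the standard ratio `R = I_A^don / I_D^don` is strictly increasing and
  convex in `phi_F` — never affine for `E > 0` — so two-point linear
  interpolation of `R` is biased (`naive_fraction_from_R()` exists
  precisely to display that bias, and `active_fraction()` refuses `R`
  without an explicit override);
* `R_alt = I_D^don / I_A^acc` is exactly affine and decreasing in `phi_F`,
  while its reciprocal is again non-affine — the orientation matters;
* both ratios are invariant under a common gain rescaling, and `R` scales
  proportionally with the acceptor gain.

`r_surface()` evaluates `R` over a grid of `x` in `[0, 0.6]` and relative
crosstalk `f_AD/f_DD` at fixed `f_AA/f_DD` (default 1, the matched-gain
condition). The surface is parameterized by the product `E * phi_F` rather
than by either factor alone: the two enter the model only through their
product, and exposing the product avoids implying otherwise.

## FLIM models

`E = (tau - tau_f)/tau` defines efficiency from donor lifetimes, and a
two-population mixture obeys `tau_mix = tau (1 - E phi_F)`; inverting the
fitted titration line gives `E = -slope/intercept`. Reported efficiencies
round to the nearest percent, matching how such values are conventionally
quoted. The frequency-domain simulator uses the phase relation `tau_phase =
tan(phase)/omega` (default modulation frequency 40 MHz, typical for
nanosecond lifetimes; reference standard 4.0 ns, the fluorescein value).
For mixtures, `simulate_phase()` sums the components' complex demodulation
responses weighted by *emitted-photon* fraction — steady-state brightness
is proportional to lifetime — a choice that must be stated explicitly
because the mixture law above weights by *molecular* fraction instead.
`phase_mixture_audit()` reports the phase lifetime against both references:
the discrepancy against the molecular-fraction average scales as `E^2` and
vanishes as `E -> 0`, while only the discrepancy against the
photon-weighted mean additionally vanishes as the modulation frequency
tends to zero. The audit is an audit, not the default estimator: the linear
mixture law is the normative model, and the audit quantifies the bias a
real phase measurement adds to it.

## Calibration

`active_fraction()` interpolates a linear observable between fully-inactive
and fully-active references; it is affine-invariant and
orientation-agnostic (works equally for decreasing observables like
`tau_mix` and `R_alt`). Interpolated fractions up to 0.02 outside `[0, 1]`
are clamped to the nearest endpoint — saturating-inhibitor calibrations are
themselves noisy, and a hard error at 1.005 would be unhelpful — while
larger excursions raise an out-of-range error; the band is configurable
because no principled universal value exists.

## Synthetic data: what is emulated, and what is not

Three designs mirror the package's reference experiments, with defaults
fixed at the study conditions: 11 equally spaced fractions, donor lifetime
2.94 ns, tandem lifetime 2.205 ns (efficiency 0.25), donor total 1000
intensity units per well.

* `tandem_vs_donor`: free donor vs tandem at constant total donor; `phi_F`
  equals the tandem fraction.
* `constant_acceptor`: free acceptor is co-added so total acceptor stays
  constant, making the `R_alt` denominator constant up to noise.
* `gtp_gdp`: a two-state probe in which every molecule carries both
  fluorophores; the GDP- and GTP-state apparent FRET fractions are
  calibrated at design construction so the noise-free standard-ratio
  endpoints are exactly 1.80 and 2.10. With the default spectra and unit
  gains that inversion would place both states above 0.6 apparent FRET —
  implausibly FRET-rich for a GTPase sensor's off state — so the
  acceptor-side detector gain (a free instrument setting in this model)
  defaults to 4, landing the calibrated states near 0.15/0.20. In that
  regime the ratio's intrinsic convexity is below 2% of the 0.3-unit span,
  which is why a genuinely non-linear readout looks effectively linear over
  a narrow operating range.

Noise model: every recorded per-wavelength scan intensity receives
independent multiplicative Gaussian noise (`intensity_cv`, default 1%,
truncated at zero), and lifetimes receive additive Gaussian noise
(`lifetime_sd`, default 0.02 ns, consistent with the +/-0.07 ns 95%
confidence scale of replicate lifetime measurements). The per-reading
placement matters: channel intensities are sums over 5–11 wavelengths, so
their effective coefficient of variation is the per-reading value shrunk by
the summation — which is what makes an 11-point `R_alt` titration at 1%
reading noise fit with R² above 0.99. Plate-reader shot and gain noise is
approximately proportional to signal; FLIM phase noise approximately
additive.

Not emulated: photobleaching of either fluorophore, detector nonlinearity
and spectral response beyond the two-level channel gain, monochromator
bandwidth, intermolecular FRET (free-acceptor spiking is simulated and, by
construction as in the reference experiments, leaves donor-excitation
observables unchanged), multi-exponential donors, and pixel-level FLIM. A
passing test suite therefore shows the estimators are correct *under the
stated forward models*, not that a given instrument satisfies those models.

## Problem sizes and reproducibility

Tests and the acceptance script use 11–21-fraction series, 100-seed
replicate ensembles for stochastic claims (200 for the unbiasedness check),
and 100 random parameter draws for the kinetics oracle equivalence — sizes
at which every statistic is stable to well within its asserted tolerance
while the whole suite runs in seconds. All randomness flows through
explicit integer seeds; identical seeds give byte-identical scan tables,
and the CSV writer formats numbers locale-independently to keep that
guarantee across platforms.
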