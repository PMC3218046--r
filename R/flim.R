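#' Donor lifetime / FRET-rate parameters
#'
#' Two equivalent parameterizations of a mono-exponential donor with FRET:
#' either the donor-only lifetime `tau_D` and per-molecule efficiency `E`,
#' or the de-excitation rate constants `k_f` (fluorescence, `tau_D = 1/k_f`)
#' and `k_et` (energy transfer), with `E = k_et / (k_f + k_et)` and the
#' FRETing lifetime `tau_f = 1 / (k_f + k_et) = tau_D * (1 - E)`.
#'
#' @param tau_D Donor-only fluorescence lifetime (ns), > 0.  Give either
#'   (`tau_D`, `E`) or (`k_f`, `k_et`).
#' @param E Per-molecule FRET efficiency, in `[0, 1)`.
#' @param k_f Fluorescence (total donor de-excitation) rate constant (1/ns).
#' @param k_et Energy-transfer rate constant (1/ns).
#' @return An object of class `lifetime_params` with fields `tau_D`, `E`,
#'   `tau_f`, `k_f`, `k_et`.
#' @examples
#' lifetime_params(tau_D = 2.94, E = 0.25)$tau_f  # 2.205 ns
#' @export
lifetime_params <- function(tau_D = NULL, E = NULL, k_f = NULL, k_et = NULL) {
  if (!is.null(tau_D) && !is.null(E)) {
    if (tau_D <= 0) stop("tau_D must be > 0", call. = FALSE)
    if (E < 0 || E >= 1) stop("E must lie in [0, 1)", call. = FALSE)
    k_f <- 1 / tau_D
    k_et <- k_f * E / (1 - E)
  } else if (!is.null(k_f) && !is.null(k_et)) {
    if (k_f <= 0) stop("k_f must be > 0", call. = FALSE)
    if (k_et < 0) stop("k_et must be >= 0", call. = FALSE)
    tau_D <- 1 / k_f
    E <- k_et / (k_f + k_et)
  } else {
    stop("supply either (tau_D, E) or (k_f, k_et)", call. = FALSE)
  }
  structure(list(tau_D = tau_D, E = E, tau_f = 1 / (k_f + k_et),
                 k_f = k_f, k_et = k_et),
            class = "lifetime_params")
}

#' @export
print.lifetime_params <- function(x, ...) {
  cat(sprintf(
    "Lifetime parameters: tau_D = %.4g ns, E = %.4g (tau_f = %.4g ns)\n",
    x$tau_D, x$E, x$tau_f))
  invisible(x)
}

#' FRET efficiency from donor lifetimes
#'
#' The standard lifetime definition of FRET efficiency,
#' `E = (tau - tau_f) / tau = 1 - tau_f / tau`, where `tau` and `tau_f` are
#' the donor lifetimes in the absence and presence of acceptor.
#'
#' @param tau Donor-only lifetime (ns), > 0.
#' @param tau_f Donor lifetime with acceptor (ns), in `[0, tau]`.
#' @return Efficiency E in `[0, 1]`.
#' @examples
#' efficiency_from_lifetimes(2.94, 2.2)  # 0.2517... ~ 25%
#' @export
efficiency_from_lifetimes <- function(tau, tau_f) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (tau_f < 0) stop("tau_f must be >= 0", call. = FALSE)
  if (tau_f > tau)
    stop("ordering error: tau_f > tau would imply negative efficiency",
         call. = FALSE)
  (tau - tau_f) / tau
}

#' Lifetime of a mixture of FRETing and non-FRETing donors
#'
#' For a mixture in which a fraction `phi_F` of donors is FRET-capable
#' (per-molecule efficiency E) and the rest are not, the measured lifetime
#' is the fractional weighted average of the components, giving the affine
#' law `E_mix = E * phi_F` and `tau_mix = tau_D * (1 - E * phi_F)`:
#' slope `-tau_D * E`, intercept `tau_D`.  This exact affinity in `phi_F`
#' is what makes FLIM a linear FRET readout.
#'
#' @param params A [lifetime_params()] object.
#' @param phi_F FRET-capable fraction(s) in `[0, 1]` (vectorized).
#' @return A list of class `mixture_lifetime` with vectors `tau_mix` (ns),
#'   `E_mix`, and the inputs.
#' @examples
#' mixture_lifetime(lifetime_params(2.94, 0.25), 1)$tau_mix  # 2.205 ns
#' @export
mixture_lifetime <- function(params, phi_F) {
  stopifnot(inherits(params, "lifetime_params"))
  if (any(phi_F < 0 | phi_F > 1))
    stop("phi_F must lie in [0, 1]", call. = FALSE)
  E_mix <- params$E * phi_F
  structure(list(tau_mix = params$tau_D * (1 - E_mix), E_mix = E_mix,
                 phi_F = phi_F, params = params),
            class = "mixture_lifetime")
}

#' Frequency-domain FLIM settings
#'
#' @param modulation_frequency Excitation modulation frequency (Hz), > 0;
#'   default 40 MHz, a typical choice for nanosecond lifetimes.
#' @param reference_lifetime Lifetime of the reference standard (ns);
#'   default 4.0 ns, the fluorescein value used to calibrate phase.
#' @return An object of class `fd_settings`.
#' @export
fd_settings <- function(modulation_frequency = 40e6,
                        reference_lifetime = 4.0) {
  if (modulation_frequency <= 0)
    stop("modulation frequency must be > 0", call. = FALSE)
  structure(list(modulation_frequency = modulation_frequency,
                 reference_lifetime = reference_lifetime),
            class = "fd_settings")
}

#' Phase lifetime from a measured phase shift
#'
#' Frequency-domain FLIM estimates lifetime from the phase shift of the
#' emission relative to the sinusoidally modulated excitation:
#' `tau_phase = tan(phase) / omega`, `omega = 2 pi f`.
#'
#' @param phase Phase shift in radians, in `[0, pi/2)`.
#' @param settings An [fd_settings()] object.
#' @return Lifetime in ns.
#' @export
phase_lifetime <- function(phase, settings = fd_settings()) {
  if (any(phase < 0 | phase >= pi / 2))
    stop("phase must lie in [0, pi/2)", call. = FALSE)
  omega <- 2 * pi * settings$modulation_frequency
  tan(phase) / omega * 1e9
}

#' Simulate the phase shift of mono- or multi-component emission
#'
#' For a single mono-exponential lifetime, the phase is `atan(omega tau)`
#' and [phase_lifetime()] inverts it exactly.  For a mixture, each
#' component's complex demodulation response `1 / (1 + i omega tau)` is
#' weighted by its emitted-photon fraction (steady-state brightness is
#' proportional to lifetime, so photon weights are
#' `fraction * tau / sum(fraction * tau)`), the responses are summed, and
#' the phase of the sum is returned.  The phase lifetime of a mixture is
#' therefore not exactly the fraction-weighted average lifetime -- the
#' systematic, frequency-dependent discrepancy quantifies the domain of
#' validity of treating the measured mixture lifetime as a weighted
#' average.
#'
#' @param lifetimes Component lifetime(s) in ns.
#' @param fractions Molecular fractions of the components (same length;
#'   default single component).  They are normalized internally.
#' @param settings An [fd_settings()] object.
#' @return Phase shift in radians.
#' @examples
#' s <- fd_settings(40e6)
#' phase_lifetime(simulate_phase(4.0, settings = s), s)  # 4.0 ns
#' @export
simulate_phase <- function(lifetimes, fractions = rep(1, length(lifetimes)),
                           settings = fd_settings()) {
  if (length(lifetimes) != length(fractions))
    stop("lifetimes and fractions must have equal length", call. = FALSE)
  if (any(lifetimes < 0) || any(fractions < 0))
    stop("lifetimes and fractions must be >= 0", call. = FALSE)
  omega <- 2 * pi * settings$modulation_frequency
  tau_s <- lifetimes * 1e-9
  w <- fractions * tau_s          # emitted-photon weights
  if (sum(w) == 0) stop("mixture emits no photons", call. = FALSE)
  w <- w / sum(w)
  resp <- sum(w / (1 + 1i * omega * tau_s))
  -Arg(resp)
}

#' Phase-lifetime audit of the weighted-average mixture model
#'
#' Signed discrepancies between the frequency-domain phase lifetime of a
#' two-component donor mixture and two reference averages: the
#' molecular-fraction-weighted lifetime that the linear FLIM mixture model
#' assumes (`tau_weighted`), and the emitted-photon-weighted mean lifetime
#' (`tau_photon`), which is what any intensity-weighted estimator
#' approaches as the modulation frequency tends to zero.  Both
#' discrepancies scale as E^2 and vanish as E -> 0; only the photon-mean
#' discrepancy additionally vanishes as the modulation frequency -> 0.
#' This quantifies the extent to which a real phase measurement is biased
#' toward the brighter, longer-lived (non-FRETing) population.
#'
#' @param params A [lifetime_params()] object.
#' @param phi_F FRET-capable fraction.
#' @param settings An [fd_settings()] object.
#' @return A list with `tau_phase`, `tau_weighted`, `tau_photon` (all ns),
#'   `discrepancy = tau_phase - tau_weighted` and
#'   `discrepancy_photon = tau_phase - tau_photon`.
#' @export
phase_mixture_audit <- function(params, phi_F, settings = fd_settings()) {
  stopifnot(inherits(params, "lifetime_params"))
  taus <- c(params$tau_D, params$tau_f)
  fr <- c(1 - phi_F, phi_F)
  ph <- simulate_phase(taus, fr, settings)
  tau_phase <- phase_lifetime(ph, settings)
  tau_weighted <- mixture_lifetime(params, phi_F)$tau_mix
  tau_photon <- sum(fr * taus^2) / sum(fr * taus)
  list(tau_phase = tau_phase, tau_weighted = tau_weighted,
       tau_photon = tau_photon,
       discrepancy = tau_phase - tau_weighted,
       discrepancy_photon = tau_phase - tau_photon)
}

#' Ordinary least-squares linearity fit of a titration series
#'
#' Fits `observable ~ fraction` by OLS and, for lifetime series, converts
#' the fitted line to a per-molecule efficiency estimate
#' `E = -slope / intercept` (the intercept estimates the donor-only
#' lifetime `tau_D` and the slope `-tau_D * E`).
#'
#' @param series A [measurement_series()] or any data frame with columns
#'   `fraction` and `observable`.
#' @param mode `"lifetime"` (report `E_estimate`) or `"ratio"`.
#' @return A list with `slope`, `intercept`, `r_squared`, `E_estimate`
#'   (`NA` for ratio mode) and the underlying `lm` fit.
#' @examples
#' s <- data.frame(fraction = seq(0, 1, 0.1),
#'                 observable = 2.94 * (1 - 0.25 * seq(0, 1, 0.1)))
#' fit_linearity(s)$E_estimate  # 0.25
#' @export
fit_linearity <- function(series, mode = c("lifetime", "ratio")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(series),
            all(c("fraction", "observable") %in% names(series)))
  if (nrow(series) < 3L || length(unique(series$fraction)) < 2L)
    stop("degenerate series: need >= 3 points with >= 2 distinct fractions",
         call. = FALSE)
  fit <- stats::lm(observable ~ fraction, data = series)
  cf <- stats::coef(fit)
  # direct R^2 (summary.lm warns on the noise-free, perfectly affine case)
  ss_tot <- sum((series$observable - mean(series$observable))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::resid(fit)^2) / ss_tot
  list(slope = unname(cf[2]), intercept = unname(cf[1]), r_squared = r2,
       E_estimate = if (mode == "lifetime") unname(-cf[2] / cf[1])
                    else NA_real_,
       fit = fit)
}
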