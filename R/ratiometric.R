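#' FRET state of a probe population
#'
#' @param E Per-molecule FRET efficiency of FRET-capable probes, in `[0, 1]`.
#' @param phi_F Fraction of donor molecules capable of transferring energy by
#'   FRET, in `[0, 1]`.  The product `E * phi_F` is the apparent fraction of
#'   FRETing molecules.
#' @return An object of class `fret_state`.
#' @export
fret_state <- function(E, phi_F) {
  stopifnot(is.numeric(E), is.numeric(phi_F), length(E) == 1L,
            length(phi_F) == 1L)
  if (E < 0 || E > 1) stop("E must lie in [0, 1]", call. = FALSE)
  if (phi_F < 0 || phi_F > 1) stop("phi_F must lie in [0, 1]", call. = FALSE)
  structure(list(E = E, phi_F = phi_F), class = "fret_state")
}

#' Excitation conditions of a two-exposure ratiometric measurement
#'
#' @param N_D_star Number of excited donor molecules under donor excitation.
#' @param N_A_direct Acceptor molecules directly excited at the donor
#'   wavelength (0 in the usual negligible-direct-excitation setting).
#' @param N_A_acc Acceptor molecules excited during the direct
#'   acceptor-excitation exposure (the denominator of R_alt).
#' @param gain_D,gain_A Per-channel detector gain multipliers.
#' @return An object of class `excitation_state`.
#' @export
excitation_state <- function(N_D_star, N_A_direct = 0, N_A_acc = 0,
                             gain_D = 1, gain_A = 1) {
  v <- c(N_D_star, N_A_direct, N_A_acc, gain_D, gain_A)
  if (any(!is.finite(v)) || any(v < 0))
    stop("all excitation-state fields must be finite and >= 0", call. = FALSE)
  structure(list(N_D_star = N_D_star, N_A_direct = N_A_direct,
                 N_A_acc = N_A_acc, gain_D = gain_D, gain_A = gain_A),
            class = "excitation_state")
}

#' Coverage coefficients of the two emission channels
#'
#' The f coefficients (photons per molecule) linking excited-molecule
#' counts to channel intensities: `f_DD` donor emission into the donor
#' channel, `f_AD` donor emission into the acceptor channel (crosstalk),
#' `f_AA` acceptor emission into the acceptor channel, and optionally
#' `f_DA` acceptor emission into the donor channel (0 by default: it is
#' ordinarily easy to exclude acceptor emission from the donor channel).
#'
#' @param f_DD,f_AD,f_AA,f_DA Coverage coefficients, >= 0.
#' @return An object of class `coverage_fractions`.
#' @seealso [coverage_from_spectra()] to derive them from spectra and bands.
#' @export
coverage_fractions <- function(f_DD, f_AD, f_AA, f_DA = 0) {
  v <- c(f_DD, f_AD, f_AA, f_DA)
  if (any(!is.finite(v)) || any(v < 0))
    stop("coverage fractions must be finite and >= 0", call. = FALSE)
  structure(list(f_DD = f_DD, f_AD = f_AD, f_AA = f_AA, f_DA = f_DA),
            class = "coverage_fractions")
}

#' Coverage coefficients from spectra and channel bands
#'
#' @param donor,acceptor [emission_spectrum()] objects.
#' @param donor_band,acceptor_band [band()]s defining the two channels;
#'   defaults are the standard donor (480-500 nm) and acceptor (525-565 nm)
#'   channels.
#' @param convention `"integral"` (trapezoid [coverage_fraction()]) or
#'   `"sum"` (5 nm band sums, [coverage_sum()], the plate-reader dialect).
#' @return A [coverage_fractions()] object.
#' @export
coverage_from_spectra <- function(donor, acceptor,
                                  donor_band = band(480, 500),
                                  acceptor_band = band(525, 565),
                                  convention = c("integral", "sum")) {
  convention <- match.arg(convention)
  f <- if (convention == "integral") coverage_fraction else coverage_sum
  coverage_fractions(f_DD = f(donor, donor_band),
                     f_AD = f(donor, acceptor_band),
                     f_AA = f(acceptor, acceptor_band),
                     f_DA = f(acceptor, donor_band))
}

#' Forward model of channel intensities
#'
#' Computes the component intensities of a two-exposure ratiometric
#' measurement.  Under donor excitation, `N_D_star * E * phi_F` excited
#' donors hand their energy to acceptors and the rest emit as donors:
#' \itemize{
#'   \item `I_DD = gain_D * N_D_star * (1 - E phi_F) * f_DD`
#'   \item `I_AD = gain_A * N_D_star * (1 - E phi_F) * f_AD`
#'   \item `I_AA = gain_A * (N_D_star * E phi_F + N_A_direct) * f_AA`
#'   \item `I_DA = gain_D * (N_D_star * E phi_F + N_A_direct) * f_DA`
#'     (0 with the default `f_DA = 0`)
#' }
#' and under the separate acceptor-excitation exposure
#' `I_A_acc = gain_A * N_A_acc * f_AA` (the donor is not excited there).
#' All components are linear in `N_D_star`.
#'
#' @param state A [fret_state()].
#' @param exc An [excitation_state()].
#' @param cov A [coverage_fractions()].
#' @return A list of class `channel_intensities` with components `I_DD`,
#'   `I_DA`, `I_AA`, `I_AD`, the channel totals `I_D_don = I_DD + I_DA`,
#'   `I_A_don = I_AA + I_AD`, and `I_A_acc`.
#' @examples
#' ci <- channel_intensities(fret_state(0.3, 0.5),
#'                           excitation_state(1000, N_A_acc = 1000),
#'                           coverage_fractions(0.4, 0.1, 0.35))
#' ci$I_D_don  # 340
#' ci$I_A_don  # 137.5
#' @export
channel_intensities <- function(state, exc, cov) {
  stopifnot(inherits(state, "fret_state"), inherits(exc, "excitation_state"),
            inherits(cov, "coverage_fractions"))
  x <- state$E * state$phi_F
  n_fret <- exc$N_D_star * x + exc$N_A_direct
  I_DD <- exc$gain_D * exc$N_D_star * (1 - x) * cov$f_DD
  I_DA <- exc$gain_D * n_fret * cov$f_DA
  I_AA <- exc$gain_A * n_fret * cov$f_AA
  I_AD <- exc$gain_A * exc$N_D_star * (1 - x) * cov$f_AD
  structure(list(I_DD = I_DD, I_DA = I_DA, I_AA = I_AA, I_AD = I_AD,
                 I_D_don = I_DD + I_DA, I_A_don = I_AA + I_AD,
                 I_A_acc = exc$gain_A * exc$N_A_acc * cov$f_AA),
            class = "channel_intensities")
}

#' The standard ratiometric FRET ratio R
#'
#' `R = I_A_don / I_D_don`: acceptor-channel over donor-channel intensity
#' under donor excitation.  With negligible direct acceptor excitation and
#' unit gains this reduces to
#' `R = [E phi_F f_AA + (1 - E phi_F) f_AD] / [(1 - E phi_F) f_DD]`,
#' which is non-linear (convex) in `phi_F` for any `E > 0, f_AA > 0` -- the
#' central caveat against calibrating standard ratiometric FRET linearly.
#'
#' @inheritParams channel_intensities
#' @param include_direct If `FALSE` (default), direct acceptor excitation at
#'   the donor wavelength is zeroed before evaluation.
#' @return The dimensionless ratio R.
#' @export
ratio_R <- function(state, exc, cov, include_direct = FALSE) {
  if (state$E * state$phi_F >= 1)
    stop("division by zero: donor channel vanishes at E * phi_F = 1",
         call. = FALSE)
  if (!include_direct)
    exc <- excitation_state(exc$N_D_star, 0, exc$N_A_acc, exc$gain_D,
                            exc$gain_A)
  ci <- channel_intensities(state, exc, cov)
  if (ci$I_D_don == 0)
    stop("division by zero: donor-channel intensity is zero", call. = FALSE)
  ci$I_A_don / ci$I_D_don
}

#' The linear alternative ratio R_alt
#'
#' `R_alt = I_D_don / I_A_acc`: donor-channel intensity under donor
#' excitation divided by acceptor-channel intensity under direct acceptor
#' excitation.  Equals
#' `gain_D N_D_star (1 - E phi_F) f_DD / (gain_A N_A_acc f_AA)` and is
#' therefore affine (decreasing) in `phi_F` at fixed everything else --
#' the property that makes two-point calibration of the active fraction
#' exact.  The same is not true of `1 / R_alt`.
#'
#' @inheritParams channel_intensities
#' @return The dimensionless ratio R_alt.
#' @export
ratio_R_alt <- function(state, exc, cov) {
  if (exc$N_A_acc * cov$f_AA == 0)
    stop("division by zero: N_A_acc * f_AA = 0 leaves no direct-acceptor signal",
         call. = FALSE)
  ci <- channel_intensities(state, exc, cov)
  ci$I_D_don / ci$I_A_acc
}

#' Simulated R surface over FRET fraction and crosstalk
#'
#' Evaluates the simplified ratio model (no direct acceptor excitation,
#' unit gains) on a grid of apparent FRET fractions `E phi_F` and relative
#' crosstalk values `f_AD / f_DD`, at a fixed `f_AA / f_DD`.  The surface is
#' strictly increasing along both axes and convex along the `E phi_F` axis
#' -- the visual demonstration that R is inherently non-linear in the
#' FRET-competent fraction.
#'
#' @param e_phi_grid Values of `E * phi_F` in `[0, 1)`; the modeled regime
#'   of interest is 0 to about 0.6.
#' @param crosstalk_grid Values of `f_AD / f_DD`, >= 0.
#' @param f_AA_over_f_DD Scalar `f_AA / f_DD` (default 1, the matched-gain
#'   condition).
#' @return A numeric matrix `R[i, j]` with rows indexed by `e_phi_grid` and
#'   columns by `crosstalk_grid`, with dimnames recording the grids.
#' @export
r_surface <- function(e_phi_grid = seq(0, 0.6, by = 0.05),
                      crosstalk_grid = seq(0, 1, by = 0.1),
                      f_AA_over_f_DD = 1) {
  if (any(e_phi_grid < 0) || any(e_phi_grid >= 1))
    stop("E * phi_F grid must lie in [0, 1)", call. = FALSE)
  if (any(crosstalk_grid < 0))
    stop("crosstalk grid must be >= 0", call. = FALSE)
  R <- outer(e_phi_grid, crosstalk_grid, function(x, c)
    (x * f_AA_over_f_DD + (1 - x) * c) / (1 - x))
  dimnames(R) <- list(e_phi = format(e_phi_grid, trim = TRUE),
                      crosstalk = format(crosstalk_grid, trim = TRUE))
  R
}

#' Naive linear interpolation of R (bias demonstrator)
#'
#' Applies the two-point linear calibration to the standard ratio R.
#' Because R is non-linear in `phi_F`, the result is a biased estimate of
#' the true FRET-competent fraction except at the endpoints; the estimator
#' exists to make that bias visible and quantifiable.
#'
#' @param R_mix Measured ratio of the mixture.
#' @param R_act,R_in Ratios of the fully FRET-competent and FRET-incompetent
#'   reference states; must differ.
#' @return `(R_mix - R_in) / (R_act - R_in)`, equal to the true fraction
#'   only when R happens to be affine in it.
#' @export
naive_fraction_from_R <- function(R_mix, R_act, R_in) {
  if (R_act == R_in)
    stop("degenerate calibration: R_act = R_in", call. = FALSE)
  (R_mix - R_in) / (R_act - R_in)
}
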