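#' Two-point calibration references
#'
#' Readings of a linear FRET observable (mixture lifetime or the
#' alternative ratio) with all probes forced fully active (`F_act`) and
#' fully inactive (`F_in`), e.g. by saturating activator/inhibitor doses.
#' Either orientation is allowed: for decreasing observables such as the
#' mixture lifetime, `F_act < F_in`.
#'
#' @param F_act Observable with all probes active.
#' @param F_in Observable with all probes inactive; must differ from
#'   `F_act`.
#' @return An object of class `calibration_pair`.
#' @export
calibration_pair <- function(F_act, F_in) {
  stopifnot(is.numeric(F_act), is.numeric(F_in), length(F_act) == 1L,
            length(F_in) == 1L, is.finite(F_act), is.finite(F_in))
  if (F_act == F_in)
    stop("degenerate calibration: F_act = F_in carries no information",
         call. = FALSE)
  structure(list(F_act = F_act, F_in = F_in), class = "calibration_pair")
}

#' Fraction of active probes from a linear FRET observable
#'
#' Linear interpolation between the fully-inactive and fully-active
#' calibration readings:
#' `phi_a = (F_mix - F_in) / (F_act - F_in)`.
#' Valid whenever the observable scales linearly with the number of
#' FRET-capable probes -- the mixture lifetime and the alternative ratio
#' R_alt, but *not* the standard ratio R.  Calling it on R therefore
#' requires an explicit override (`allow_nonlinear = TRUE`), which routes
#' through [naive_fraction_from_R()] so the resulting bias is visible by
#' construction.
#'
#' Values slightly outside `[0, 1]` (within `clamp`) are clamped to the
#' nearest endpoint, absorbing measurement noise at the calibration
#' endpoints; beyond the band an out-of-range error is raised.
#'
#' @param F_mix Measured observable of the mixture (vectorized).
#' @param cal A [calibration_pair()].
#' @param observable `"tau"`, `"ralt"` (both linear) or `"R"` (refused
#'   without the override).
#' @param allow_nonlinear Set `TRUE` to force interpolation of the standard
#'   ratio R despite its non-linearity.
#' @param clamp Tolerated excursion outside `[0, 1]` before erroring
#'   (default 0.02).
#' @return Active-probe fraction(s) `phi_a` in `[0, 1]`.
#' @examples
#' cal <- calibration_pair(F_act = 2.205, F_in = 2.94)
#' active_fraction(2.5, cal)  # ~ 0.599
#' @export
active_fraction <- function(F_mix, cal, observable = c("tau", "ralt", "R"),
                            allow_nonlinear = FALSE, clamp = 0.02) {
  stopifnot(inherits(cal, "calibration_pair"))
  observable <- match.arg(observable)
  if (observable == "R" && !allow_nonlinear)
    stop(paste("the standard ratio R is non-linear in the FRET-capable",
               "fraction, so two-point interpolation is biased; set",
               "allow_nonlinear = TRUE to compute the (biased) naive",
               "estimate anyway"), call. = FALSE)
  phi <- (F_mix - cal$F_in) / (cal$F_act - cal$F_in)
  out_of_band <- phi < -clamp | phi > 1 + clamp
  if (any(out_of_band))
    stop(sprintf(
      "out of range: interpolated fraction %.4g lies more than %.3g outside [0, 1]; check the calibration endpoints",
      phi[which(out_of_band)[1]], clamp), call. = FALSE)
  pmin(pmax(phi, 0), 1)
}

#' Invert a fitted linear observable to the FRET-capable fraction
#'
#' Algebraic inversion of a fitted titration line:
#' `phi_F = (observable - intercept) / slope`.  Equivalent to
#' [active_fraction()] with calibration endpoints `intercept` (fraction 0)
#' and `intercept + slope` (fraction 1).
#'
#' @param fit A list with `slope` and `intercept` (e.g. from
#'   [fit_linearity()]); `slope` must be non-zero.
#' @param observable_value Observed value(s) to invert.
#' @return Estimated fraction(s); not clamped.
#' @export
invert_linear_observable <- function(fit, observable_value) {
  if (!is.list(fit) || is.null(fit$slope) || is.null(fit$intercept))
    stop("fit must supply 'slope' and 'intercept'", call. = FALSE)
  if (fit$slope == 0) stop("zero slope: line is not invertible", call. = FALSE)
  (observable_value - fit$intercept) / fit$slope
}
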