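#' Design of a synthetic mixture-titration experiment
#'
#' Describes one of the three in-vitro mixture experiments the simulators
#' emulate:
#' \describe{
#'   \item{`gtp_gdp`}{mixtures of the GTP- (active) and GDP- (inactive)
#'     locked states of a unimolecular GTPase probe; every molecule carries
#'     both fluorophores, and the two states differ by a small per-molecule
#'     efficiency difference.  The per-state efficiencies are calibrated at
#'     construction so the noise-free standard-ratio endpoints are 1.80 and
#'     2.10 (the regime in which the inherently non-linear ratio looks
#'     effectively linear).}
#'   \item{`tandem_vs_donor`}{dilution series of free donor vs
#'     donor-acceptor tandem fusion at constant total donor; the
#'     FRET-capable fraction equals the tandem fraction.}
#'   \item{`constant_acceptor`}{as `tandem_vs_donor`, but free acceptor is
#'     co-added so the total acceptor (monomer plus tandem) stays constant
#'     across the series -- the design that makes the directly-excited
#'     acceptor intensity, and hence the R_alt denominator, constant up to
#'     noise.}
#' }
#'
#' @param kind One of `"gtp_gdp"`, `"tandem_vs_donor"`,
#'   `"constant_acceptor"`.
#' @param n_points Number of fractions (default 11).
#' @param fractions FRET-capable (or GTP-bound) fractions, sorted, in
#'   `[0, 1]`; default equally spaced on `[0, 1]`.
#' @param E Per-molecule efficiency of the tandem / fully-active species
#'   (default 0.25, the tandem-fusion value).
#' @param tau_D Donor-only lifetime in ns (default 2.94).
#' @param donor,acceptor [emission_spectrum()] objects; defaults from
#'   [default_spectra()].
#' @param N_total Total probe (donor-containing) amount per well, in
#'   excited-molecule units (default 1000).
#' @param intensity_cv Relative standard deviation of the multiplicative
#'   Gaussian noise applied to every recorded per-wavelength scan intensity
#'   (default 0.01).
#' @param lifetime_sd Additive Gaussian noise on lifetimes, ns
#'   (default 0.02).
#' @param extra_acceptor Free acceptor added per well in the same units
#'   (default 0); visible only in the direct-acceptor exposure.
#' @param gain_A Detector gain of the acceptor-side emission region
#'   (recorded wavelengths >= 515 nm) relative to the donor region.  Gains
#'   are free instrument settings; the default of 4 is chosen so that the
#'   `gtp_gdp` endpoint calibration lands at per-state apparent FRET
#'   fractions typical of small-GTPase sensors (about 0.15 inactive, 0.20
#'   active) rather than the implausibly FRET-rich states implied by unit
#'   gain.
#' @param r_endpoints Noise-free standard-ratio endpoints used to calibrate
#'   the `gtp_gdp` per-state efficiencies (default `c(1.80, 2.10)`).
#' @param seed Integer RNG seed; identical seeds give identical tables.
#' @return An object of class `mixture_design`.
#' @export
mixture_design <- function(kind = c("gtp_gdp", "tandem_vs_donor",
                                    "constant_acceptor"),
                           n_points = 11L,
                           fractions = seq(0, 1, length.out = n_points),
                           E = 0.25, tau_D = 2.94,
                           donor = default_spectra()$donor,
                           acceptor = default_spectra()$acceptor,
                           N_total = 1000,
                           intensity_cv = 0.01, lifetime_sd = 0.02,
                           extra_acceptor = 0,
                           gain_A = 4,
                           r_endpoints = c(1.80, 2.10),
                           seed = 42L) {
  kind <- match.arg(kind)
  fractions <- as.numeric(fractions)
  if (is.unsorted(fractions) || any(fractions < 0 | fractions > 1))
    stop("fractions must be sorted within [0, 1]", call. = FALSE)
  if (intensity_cv < 0 || lifetime_sd < 0)
    stop("noise parameters must be >= 0", call. = FALSE)
  if (N_total <= 0)
    stop("design inconsistency: N_total must be > 0", call. = FALSE)
  if (gain_A <= 0)
    stop("design inconsistency: gain_A must be > 0", call. = FALSE)
  des <- structure(
    list(kind = kind, fractions = fractions, E = E, tau_D = tau_D,
         donor = donor, acceptor = acceptor, N_total = N_total,
         intensity_cv = intensity_cv, lifetime_sd = lifetime_sd,
         extra_acceptor = extra_acceptor, gain_A = gain_A,
         seed = as.integer(seed)),
    class = "mixture_design")
  if (kind == "gtp_gdp") {
    st <- calibrate_two_state(donor, acceptor, r_endpoints, gain_A = gain_A)
    des$E_off <- st[1]; des$E_on <- st[2]
  }
  des
}

#' @export
print.mixture_design <- function(x, ...) {
  cat(sprintf("Mixture design '%s': %d fractions, E = %g, seed %d\n",
              x$kind, length(x$fractions), x$E, x$seed))
  if (x$kind == "gtp_gdp")
    cat(sprintf("  calibrated per-state efficiencies: E_off = %.4g, E_on = %.4g\n",
                x$E_off, x$E_on))
  invisible(x)
}

# Per-state apparent FRET fractions of a two-state probe, calibrated so the
# noise-free standard ratio (nominal FRET channel over donor channel, band
# sums, acceptor-side gain applied) hits the requested endpoints.
calibrate_two_state <- function(donor, acceptor, r_endpoints,
                                fret_band = band(515, 565),
                                donor_band = band(480, 500),
                                gain_A = 1) {
  cov <- coverage_from_spectra(donor, acceptor, donor_band, fret_band,
                               convention = "sum")
  # gain multiplies everything recorded in the acceptor-side band
  f_AA <- gain_A * cov$f_AA; f_AD <- gain_A * cov$f_AD
  x_of_R <- function(R) {
    (R * cov$f_DD - f_AD) /
      (f_AA - f_AD + R * (cov$f_DD - cov$f_DA))
  }
  x <- vapply(sort(r_endpoints), x_of_R, numeric(1))
  if (any(x <= 0 | x >= 1) || x[1] >= x[2])
    stop("design inconsistency: ratio endpoints are not reachable with these spectra",
         call. = FALSE)
  x
}

# apparent FRET fraction E*phi at each design fraction
apparent_fret_fraction <- function(design) {
  switch(design$kind,
    gtp_gdp = (1 - design$fractions) * design$E_off +
              design$fractions * design$E_on,
    design$E * design$fractions)
}

# directly-excited acceptor amount at each design fraction
acceptor_amount <- function(design) {
  n <- length(design$fractions)
  base <- switch(design$kind,
    gtp_gdp = rep(design$N_total, n),
    tandem_vs_donor = design$N_total * design$fractions,
    constant_acceptor = rep(design$N_total, n))
  base + design$extra_acceptor
}

#' Simulate a plate-reader emission scan of a mixture series
#'
#' One well per design fraction, two exposures per well, emulating the
#' plate protocol: donor/FRET excitation at 436 nm with emission scanned
#' 480-565 nm, and direct acceptor excitation at 505 nm scanned
#' 525-565 nm, both at 5 nm intervals.  Under donor excitation a fraction
#' `E * phi_F` of excited donors transfers to the acceptor, so each
#' wavelength reads the corresponding blend of the two (sampled) emission
#' spectra.  Multiplicative Gaussian noise of relative sd `intensity_cv`
#' is applied independently to every recorded intensity (negative draws
#' are truncated at zero); channel intensities are sums of these readings,
#' so their effective noise shrinks with the number of wavelengths summed.
#' Readings at emission wavelengths of 515 nm and above carry the
#' acceptor-side detector gain `gain_A`.
#'
#' @param design A [mixture_design()].
#' @return A scan table (`data.frame` with columns `well`, `excitation_nm`,
#'   `emission_nm`, `intensity`) suitable for [channel_sum()] and
#'   [write_scan()].
#' @export
generate_scan_plate <- function(design) {
  stopifnot(inherits(design, "mixture_design"))
  if (design$kind == "constant_acceptor" &&
      design$N_total + design$extra_acceptor <= 0)
    stop("design inconsistency: constant_acceptor needs a non-zero acceptor pool",
         call. = FALSE)
  set.seed(design$seed)
  x <- apparent_fret_fraction(design)
  n_acc <- acceptor_amount(design)
  N <- design$N_total
  don_grid <- seq(480, 565, by = 5)
  acc_grid <- seq(525, 565, by = 5)
  dens_at <- function(sp, grid)
    sp$quantum_yield * stats::approx(sp$wavelengths, sp$density,
                                     xout = grid, yleft = 0, yright = 0)$y
  dd_don <- dens_at(design$donor, don_grid)
  da_don <- dens_at(design$acceptor, don_grid)
  da_acc <- dens_at(design$acceptor, acc_grid)
  # acceptor-side detector gain applies to recorded wavelengths >= 515 nm
  g_don <- ifelse(don_grid >= 515, design$gain_A, 1)
  g_acc <- ifelse(acc_grid >= 515, design$gain_A, 1)
  wells <- sprintf("W%02d", seq_along(design$fractions))
  rows <- vector("list", 2L * length(wells))
  for (i in seq_along(wells)) {
    don_I <- (N * (1 - x[i]) * dd_don + N * x[i] * da_don) * g_don
    acc_I <- n_acc[i] * da_acc * g_acc
    rows[[2L * i - 1L]] <- data.frame(
      well = wells[i], excitation_nm = 436, emission_nm = don_grid,
      intensity = don_I)
    rows[[2L * i]] <- data.frame(
      well = wells[i], excitation_nm = 505, emission_nm = acc_grid,
      intensity = acc_I)
  }
  tab <- do.call(rbind, rows)
  if (design$intensity_cv > 0)
    tab$intensity <- pmax(0, tab$intensity *
                               (1 + stats::rnorm(nrow(tab),
                                                 sd = design$intensity_cv)))
  attr(tab, "fractions") <- stats::setNames(design$fractions, wells)
  tab
}

#' Construct a measurement series
#'
#' The unit of linearity fitting: matched vectors of FRET-capable
#' fractions and observable readings.
#'
#' @param fractions Fractions in `[0, 1]`.
#' @param observable Matched observable readings (`tau_mix` in ns, or a
#'   ratio).
#' @param kind Label of the observable (`"tau"`, `"R"` or `"R_alt"`).
#' @param noise_sd Noise scale used to generate it, in observable units.
#' @return A data frame of class `measurement_series` with columns
#'   `fraction`, `observable`.
#' @export
measurement_series <- function(fractions, observable, kind = "tau",
                               noise_sd = NA_real_) {
  if (length(fractions) != length(observable))
    stop("fractions and observable must have equal length", call. = FALSE)
  if (any(fractions < 0 | fractions > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  structure(data.frame(fraction = fractions, observable = observable),
            class = c("measurement_series", "data.frame"),
            kind = kind, noise_sd = noise_sd)
}

#' Generate a synthetic titration series
#'
#' Draws one realization of the designed mixture experiment and reduces it
#' to a (fraction, observable) series:
#' \itemize{
#'   \item `"tau"`: the mixture lifetime `tau_D * (1 - E phi_F)` plus
#'     additive Gaussian noise of sd `lifetime_sd`;
#'   \item `"R"`: channel sums of a simulated scan plate, nominal FRET
#'     channel (515-565 nm) over donor channel (480-500 nm) under donor
#'     excitation;
#'   \item `"R_alt"`: donor channel under donor excitation over acceptor
#'     channel (525-565 nm) under direct acceptor excitation.
#' }
#' Ratio observables inherit their noise from the per-wavelength scan
#' noise, so identical seeds give series identical to the channel sums of
#' [generate_scan_plate()].
#'
#' @param design A [mixture_design()].
#' @param observable `"tau"`, `"R"` or `"R_alt"`.
#' @return A [measurement_series()].
#' @examples
#' d <- mixture_design("tandem_vs_donor", lifetime_sd = 0, seed = 1)
#' generate_series(d, "tau")  # exactly the mixture-lifetime line
#' @export
generate_series <- function(design, observable = c("tau", "R", "R_alt")) {
  stopifnot(inherits(design, "mixture_design"))
  observable <- match.arg(observable)
  if (observable == "tau") {
    set.seed(design$seed)
    x <- apparent_fret_fraction(design)
    tau <- design$tau_D * (1 - x)
    if (design$lifetime_sd > 0)
      tau <- tau + stats::rnorm(length(tau), sd = design$lifetime_sd)
    return(measurement_series(design$fractions, tau, "tau",
                              design$lifetime_sd))
  }
  plate <- generate_scan_plate(design)
  bands <- default_bands()
  num_band <- if (observable == "R") bands$fret else bands$donor
  den_exc <- if (observable == "R") 436 else 505
  num_exc <- 436
  den_band <- if (observable == "R") bands$donor else bands$acceptor
  wells <- unique(plate$well)
  obs <- vapply(wells, function(w) {
    num <- channel_sum(plate[plate$well == w & plate$excitation_nm == num_exc, ],
                       num_band)
    den <- channel_sum(plate[plate$well == w & plate$excitation_nm == den_exc, ],
                       den_band)
    if (den == 0)
      stop("design inconsistency: zero denominator intensity in well ", w,
           call. = FALSE)
    num / den
  }, numeric(1))
  measurement_series(design$fractions, unname(obs),
                     if (observable == "R") "R" else "R_alt",
                     design$intensity_cv)
}
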