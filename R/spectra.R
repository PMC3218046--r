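#' Emission channel definitions (plate-reader band sums)
#'
#' The three emission channels used throughout: donor 480-500 nm, acceptor
#' 525-565 nm, and the nominal FRET channel 515-565 nm, all closed intervals
#' summed inclusively on the native 5 nm sample grid.
#'
#' @format A named list of [band()] objects: `donor`, `acceptor`, `fret`.
#' @export
default_bands <- function() {
  list(donor = band(480, 500), acceptor = band(525, 565),
       fret = band(515, 565))
}

#' An emission wavelength band
#'
#' Bands are closed intervals `[lo, hi]` in nm; band sums on sampled scans
#' include both endpoints.
#'
#' @param lo,hi Band edges in nm, `lo <= hi`.
#' @return An object of class `band`.
#' @export
band <- function(lo, hi) {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1L,
            length(hi) == 1L, is.finite(lo), is.finite(hi))
  if (lo > hi) stop("band requires lo <= hi", call. = FALSE)
  structure(list(lo = lo, hi = hi), class = "band")
}

#' @export
print.band <- function(x, ...) {
  cat(sprintf("Emission band [%g, %g] nm\n", x$lo, x$hi)); invisible(x)
}

#' Construct an emission spectrum
#'
#' @param wavelengths Strictly increasing wavelength grid (nm).
#' @param density Non-negative emission density per nm on the grid; it is
#'   renormalized so its trapezoid integral over the grid is 1.
#' @param quantum_yield Photons emitted per excited molecule, in (0, 1].
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelengths, density, quantum_yield = 1) {
  wavelengths <- as.numeric(wavelengths)
  density <- as.numeric(density)
  if (length(wavelengths) < 2L || any(diff(wavelengths) <= 0))
    stop("wavelengths must be a strictly increasing grid of length >= 2",
         call. = FALSE)
  if (length(density) != length(wavelengths))
    stop("density and wavelengths must have equal length", call. = FALSE)
  if (any(density < 0)) stop("density must be non-negative", call. = FALSE)
  if (!is.numeric(quantum_yield) || quantum_yield <= 0 || quantum_yield > 1)
    stop("quantum_yield must lie in (0, 1]", call. = FALSE)
  z <- trapz(wavelengths, density)
  if (z <= 0) stop("density integrates to zero", call. = FALSE)
  structure(list(wavelengths = wavelengths, density = density / z,
                 quantum_yield = quantum_yield),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf(
    "Emission spectrum: %d points, %g-%g nm, peak %g nm, QY %.3g\n",
    length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
    x$wavelengths[which.max(x$density)], x$quantum_yield))
  invisible(x)
}

# trapezoid rule on an irregular grid
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Parametric synthetic emission spectrum
#'
#' Generates a smooth fluorescent-protein-like emission spectrum: a
#' log-normal shape in wavelength with its mode at `peak`, Gaussian-limit
#' width `width`, and a shape parameter `skew` controlling the red tail
#' (`skew = 0` gives a symmetric Gaussian; typical FP emission has a
#' pronounced red tail, `skew` around 0.2-0.4).  The density is renormalized
#' to unit trapezoid integral on the stored grid.
#'
#' Real mTFP1/mVenus spectra are not bundled; these stand-ins place the
#' peaks at literature-typical wavelengths, and only ratios of band
#' integrals enter any downstream model.
#'
#' @param peak Mode wavelength (nm).
#' @param width Gaussian-limit standard deviation (nm), > 0.
#' @param skew Dimensionless log-normal shape parameter, >= 0.
#' @param quantum_yield Photons per excited molecule, in (0, 1].
#' @param grid Wavelength grid (nm); default 1 nm steps over 400-700 nm.
#' @return An [emission_spectrum()].
#' @examples
#' donor <- synth_emission_spectrum(492, 14, skew = 0.35, quantum_yield = 0.85)
#' @export
synth_emission_spectrum <- function(peak, width, skew = 0, quantum_yield = 1,
                                    grid = seq(400, 700, by = 1)) {
  if (!is.numeric(width) || width <= 0)
    stop("invalid parameter: width must be > 0", call. = FALSE)
  if (skew < 0) stop("invalid parameter: skew must be >= 0", call. = FALSE)
  if (skew < 1e-8) {
    dens <- exp(-((grid - peak)^2) / (2 * width^2))
  } else {
    # three-parameter log-normal: mode at `peak`, Gaussian-limit sd `width`
    s <- skew
    scale <- width / s              # exp(mu)
    theta <- peak - scale * exp(-s^2)  # location shift
    x <- grid - theta
    dens <- numeric(length(grid))
    pos <- x > 0
    dens[pos] <- exp(-(log(x[pos] / scale))^2 / (2 * s^2)) / x[pos]
  }
  emission_spectrum(grid, dens, quantum_yield)
}

#' Fraction of emission captured by a band (photons per molecule)
#'
#' The coverage coefficient of a band: quantum yield times the trapezoid
#' integral of the normalized emission density over `[lo, hi]`, with linear
#' interpolation at band edges that fall between grid points.  This is the
#' physical counterpart of the f coefficients (f_DD, f_AD, f_AA) linking
#' excited-molecule counts to channel intensities; detector gains are
#' modeled separately in the ratiometric module.
#'
#' @param spectrum An [emission_spectrum()].
#' @param band A [band()]; bands partially or wholly outside the grid
#'   contribute only their overlap, and zero-width bands return 0.
#' @return Photons per molecule captured by the band (scalar >= 0).
#' @examples
#' d <- synth_emission_spectrum(492, 15)
#' coverage_fraction(d, band(480, 500))
#' @export
coverage_fraction <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "emission_spectrum"), inherits(band, "band"))
  w <- spectrum$wavelengths
  lo <- max(band$lo, min(w)); hi <- min(band$hi, max(w))
  if (lo >= hi) return(0)
  inner <- w[w > lo & w < hi]
  xs <- c(lo, inner, hi)
  ys <- stats::approx(w, spectrum$density, xout = xs)$y
  spectrum$quantum_yield * trapz(xs, ys)
}

#' Band-sum coverage coefficient on the 5 nm plate grid
#'
#' The plate-reader dialect of [coverage_fraction()]: quantum yield times
#' the plain sum of the sampled emission density at the 5 nm grid points
#' inside the closed band.  Channel sums of simulated scans reproduce model
#' ratios exactly under this convention (sums, not integrals, are what the
#' instrument reports).
#'
#' @inheritParams coverage_fraction
#' @param step Sample grid step (nm), default 5.
#' @return Photons per molecule in sum convention.
#' @export
coverage_sum <- function(spectrum, band, step = 5) {
  stopifnot(inherits(spectrum, "emission_spectrum"), inherits(band, "band"))
  grid <- seq(band$lo, band$hi, by = step)
  ys <- stats::approx(spectrum$wavelengths, spectrum$density, xout = grid,
                      yleft = 0, yright = 0)$y
  spectrum$quantum_yield * sum(ys)
}

#' Sum a scan over an emission channel
#'
#' Sums the recorded intensities at the 5 nm grid wavelengths lying in the
#' closed band, per the plate-reader channel definitions (e.g. donor channel
#' = sum from 480 to 500 nm inclusive).
#'
#' @param scan A scan table (see [read_scan()]) or any data frame with
#'   columns `emission_nm` and `intensity`; typically pre-filtered to one
#'   well and one excitation.
#' @param band A [band()] whose edges lie on the 5 nm grid.
#' @return Summed intensity (a.u.).
#' @export
channel_sum <- function(scan, band) {
  stopifnot(is.data.frame(scan), inherits(band, "band"))
  if (band$lo %% 5 != 0 || band$hi %% 5 != 0)
    stop(sprintf("grid mismatch: band [%g, %g] endpoints must lie on the 5 nm grid",
                 band$lo, band$hi), call. = FALSE)
  keep <- scan$emission_nm >= band$lo & scan$emission_nm <= band$hi
  sum(scan$intensity[keep])
}

#' FRET-channel overlap-index series
#'
#' Reproduces the variable-overlap construction: FRET channels
#' `[535,565], [530,565], ..., [480,565]` (twelve 5 nm extensions of the
#' band lower edge), each paired with an overlap index proportional to
#' f_AD/f_DD -- here the donor coverage of the FRET band divided by the
#' donor coverage of the donor channel (480-500 nm).  The index is
#' non-decreasing as the band lower edge moves down.
#'
#' @param donor Donor [emission_spectrum()], defined over 480-565 nm.
#' @param acceptor Acceptor [emission_spectrum()] (carried along for
#'   convenience; the index itself depends only on the donor).
#' @return A data frame with columns `lo`, `hi`, `overlap_index`, and the
#'   acceptor coverage `f_AA` of each band.
#' @export
overlap_index_series <- function(donor, acceptor = NULL) {
  stopifnot(inherits(donor, "emission_spectrum"))
  los <- seq(535, 480, by = -5)
  f_ref <- coverage_fraction(donor, band(480, 500))
  rows <- lapply(los, function(lo) {
    b <- band(lo, 565)
    data.frame(lo = lo, hi = 565,
               overlap_index = coverage_fraction(donor, b) / f_ref,
               f_AA = if (is.null(acceptor)) NA_real_
                      else coverage_fraction(acceptor, b))
  })
  do.call(rbind, rows)
}

#' Default donor/acceptor spectrum fixtures
#'
#' Log-normal stand-ins for the mTFP1 donor (peak 492 nm) and mVenus
#' acceptor (peak 528 nm) with literature-typical quantum yields.
#'
#' @return A list with elements `donor` and `acceptor`.
#' @export
default_spectra <- function() {
  list(donor = synth_emission_spectrum(492, 14, skew = 0.35,
                                       quantum_yield = 0.85),
       acceptor = synth_emission_spectrum(528, 14, skew = 0.35,
                                          quantum_yield = 0.57))
}
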