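#' Instrument configuration for lamellar diffraction corrections
#'
#' Geometry and absorption parameters entering the Lorentz, absorption and
#' flux corrections of a monochromatic reflectometry-style measurement.
#'
#' @param wavelength neutron wavelength, Angstrom.
#' @param sample_thickness sample film thickness t, cm.
#' @param sample_length sample length l along the beam footprint, mm.
#' @param beam_sigma half of the beam width (beam width = 2 sigma), mm.
#' @param mu linear absorption coefficient, 1/cm. Depends on the lipid, the
#'   sample thickness and the D2O/H2O ratio; supply per contrast when known.
#' @param flux_denominator `"as-printed"` uses erf(l sin(theta) / (8 sigma));
#'   `"gaussian"` uses erf(l sin(theta) / (sqrt(8) sigma)), the Gaussian-beam
#'   reading of the same expression.
#' @return object of class `instrument_config`.
#' @examples
#' instrument_config()
#' @export
instrument_config <- function(wavelength = 4.5707,
                              sample_thickness = 0.001,
                              sample_length = 65,
                              beam_sigma = 2,
                              mu = 1.0,
                              flux_denominator = c("as-printed", "gaussian")) {
  flux_denominator <- match.arg(flux_denominator)
  stopifnot(wavelength > 0, sample_thickness > 0, sample_length > 0,
            beam_sigma > 0, mu >= 0)
  structure(list(wavelength = wavelength,
                 sample_thickness = sample_thickness,
                 sample_length = sample_length,
                 beam_sigma = beam_sigma,
                 mu = mu,
                 flux_denominator = flux_denominator),
            class = "instrument_config")
}

#' Lorentz factor for a lamellar reflection
#'
#' `L_f = 1 / sin(2 theta_h)` for a monochromatic beam.
#'
#' @param theta_rad Bragg angle theta (not 2 theta) in radians, in (0, pi/2).
#' @return dimensionless correction factor.
#' @examples
#' lorentz_factor(pi / 4)  # 1
#' @export
lorentz_factor <- function(theta_rad) {
  if (any(theta_rad <= 0) || any(theta_rad >= pi / 2))
    stop("lorentz_factor: theta must be in (0, 90 deg); sin(2 theta) is singular at the ends")
  1 / sin(2 * theta_rad)
}

#' Absorption correction for a thin aligned film
#'
#' `A_c = sin(theta) / (2 mu t) * (1 - exp(-2 mu t / sin(theta)))`,
#' the transmission average over the beam path in a film of thickness t with
#' linear absorption coefficient mu. Continuous at mu t -> 0 (A_c -> 1); a
#' series branch is used for small arguments to avoid cancellation.
#'
#' @param theta_rad Bragg angle in radians, in (0, pi/2].
#' @param mu linear absorption coefficient, 1/cm (>= 0).
#' @param t sample thickness, cm (> 0).
#' @return value in (0, 1].
#' @export
absorption_factor <- function(theta_rad, mu, t) {
  if (any(mu < 0)) stop("absorption_factor: mu must be >= 0")
  if (any(t <= 0)) stop("absorption_factor: t must be > 0")
  if (any(theta_rad <= 0) || any(theta_rad > pi / 2))
    stop("absorption_factor: theta must be in (0, 90 deg]")
  u <- 2 * mu * t / sin(theta_rad)   # dimensionless optical depth
  small <- u < 1e-6
  out <- u
  # (1 - exp(-u))/u; series 1 - u/2 + u^2/6 below the branch threshold
  out[small] <- 1 - u[small] / 2 + u[small]^2 / 6
  out[!small] <- (1 - exp(-u[!small])) / u[!small]
  out
}

#' Beam flux (footprint) correction
#'
#' `F_c = erf(l sin(theta) / (8 sigma))` as printed for a sample of length l
#' in a beam of width 2 sigma; the fraction of the beam intercepted by the
#' sample footprint at angle theta. The `"gaussian"` variant replaces the
#' denominator by sqrt(8) sigma (see [instrument_config]).
#'
#' @param theta_rad Bragg angle in radians.
#' @param l sample length, mm.
#' @param sigma half beam width, mm.
#' @param denominator `"as-printed"` or `"gaussian"`.
#' @return value in [0, 1), monotone increasing in `l * sin(theta)`.
#' @export
flux_factor <- function(theta_rad, l, sigma,
                        denominator = c("as-printed", "gaussian")) {
  denominator <- match.arg(denominator)
  stopifnot(l > 0, sigma > 0)
  den <- if (denominator == "as-printed") 8 * sigma else sqrt(8) * sigma
  pracma::erf(l * sin(theta_rad) / den)
}

#' Combined correction factor for one reflection
#' @inheritParams lorentz_factor
#' @param instrument an [instrument_config].
#' @param mu optional override of the instrument's absorption coefficient
#'   (1/cm), e.g. per contrast.
#' @return `L_f * A_c * F_c`.
#' @export
correction_factor <- function(theta_rad, instrument, mu = instrument$mu) {
  lorentz_factor(theta_rad) *
    absorption_factor(theta_rad, mu, instrument$sample_thickness) *
    flux_factor(theta_rad, instrument$sample_length, instrument$beam_sigma,
                instrument$flux_denominator)
}

#' Structure factor magnitude from an integrated intensity
#'
#' `|F_h| = sqrt(I_h / (L_f A_c F_c))` with uncertainty propagated from the
#' intensity: `sigma_F = sigma_I / (2 |F_h| L_f A_c F_c)`.
#'
#' @param I_h integrated, monitor-normalized intensity (>= 0).
#' @param L_f,A_c,F_c correction factors (> 0); see [lorentz_factor],
#'   [absorption_factor], [flux_factor].
#' @param sigma_I intensity uncertainty (optional).
#' @return data.frame with columns `F_mag` and `F_sigma` (NA when sigma_I is
#'   missing; Inf relative uncertainty flagged as `F_sigma = Inf` at I = 0).
#' @export
structure_factor_magnitude <- function(I_h, L_f, A_c, F_c, sigma_I = NA_real_) {
  if (any(I_h < 0)) stop("structure_factor_magnitude: negative intensity")
  corr <- L_f * A_c * F_c
  if (any(!is.finite(corr)) || any(corr <= 0))
    stop("structure_factor_magnitude: correction factors must be positive and finite")
  F_mag <- sqrt(I_h / corr)
  F_sigma <- ifelse(F_mag > 0, sigma_I / (2 * F_mag * corr),
                    ifelse(is.na(sigma_I), NA_real_, Inf))
  data.frame(F_mag = F_mag, F_sigma = F_sigma)
}

#' Bragg angle of order h
#'
#' theta_h = asin(h lambda / (2 D)); undefined (NA) when h lambda / (2 D) > 1.
#'
#' @param h diffraction order(s).
#' @param D lamellar repeat distance, Angstrom.
#' @param wavelength neutron wavelength, Angstrom.
#' @return theta in radians (NA where the reflection does not exist).
#' @export
bragg_theta <- function(h, D, wavelength) {
  stopifnot(D > 0, wavelength > 0)
  s <- h * wavelength / (2 * D)
  out <- rep(NA_real_, length(s))
  out[s <= 1] <- asin(s[s <= 1])
  out
}
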