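#' Coherent neutron scattering lengths and default molecular volumes
#'
#' Bound coherent scattering lengths (fm) for the elements needed to compute
#' water scattering length densities, plus default molecular volumes (cubic
#' Angstrom) for water, DOPC and aliphatic alcohols. The volumes are
#' literature-typical fluid-phase values and are meant to be overridden when
#' sample-specific volumetry is available.
#'
#' @format A named list:
#' \describe{
#'   \item{b_H, b_D, b_C, b_N, b_O, b_P}{coherent scattering lengths, fm}
#'   \item{V_water}{molecular volume of water, Angstrom^3}
#'   \item{V_DOPC}{molecular volume of DOPC, Angstrom^3}
#'   \item{b_DOPC}{total coherent scattering length of DOPC, fm}
#'   \item{V_CH2, V_CH3, V_OH}{group volumes for alcohol tails, Angstrom^3}
#' }
#' @export
scattering_constants <- list(
  b_H = -3.7406,  # fm
  b_D =  6.671,
  b_C =  6.6460,
  b_N =  9.36,
  b_O =  5.803,
  b_P =  5.13,
  V_water = 30.0,   # A^3 at 25 C
  V_DOPC  = 1303.0, # A^3, fluid phase
  # DOPC C44H84NO8P total coherent scattering length
  b_DOPC  = 44 * 6.6460 + 84 * (-3.7406) + 9.36 + 8 * 5.803 + 5.13,
  V_CH2 = 26.9,
  V_CH3 = 54.0,
  V_OH  = 12.0
)

#' Neutron scattering length density of D2O/H2O mixtures
#'
#' Computes the NSLD of water at a given D2O mole fraction from the coherent
#' scattering lengths of H, D and O and the molecular volume of water.
#' Units are 1e-6 Angstrom^-2 throughout the package (1 fm / 30 A^3 =
#' 0.333e-6 A^-2).
#'
#' @param d2o_fraction D2O mole fraction of the hydrating water, in [0, 1].
#' @param V_water molecular volume of water in Angstrom^3.
#' @param constants list of scattering lengths, see [scattering_constants].
#' @return NSLD in units of 1e-6 Angstrom^-2.
#' @examples
#' water_nsld(0.5)
#' water_nsld(contrast_match_fraction())  # ~0 by construction
#' @export
water_nsld <- function(d2o_fraction, V_water = scattering_constants$V_water,
                       constants = scattering_constants) {
  stopifnot(all(d2o_fraction >= 0), all(d2o_fraction <= 1), V_water > 0)
  b_mix <- 2 * ((1 - d2o_fraction) * constants$b_H + d2o_fraction * constants$b_D) +
    constants$b_O
  # fm / A^3 -> 1e-6 A^-2: 1 fm = 1e-5 A, so b/V [A^-2] = b_fm * 1e-5 / V;
  # in units of 1e-6 A^-2 that is b_fm * 10 / V.
  10 * b_mix / V_water
}

#' D2O fraction at which water NSLD vanishes
#'
#' The contrast-match point of water: close to 8 percent D2O, which is why
#' lamellar diffraction at 8 percent D2O suppresses the water contribution
#' and exposes the bilayer-only profile.
#'
#' @inheritParams water_nsld
#' @return D2O mole fraction in (0, 1).
#' @export
contrast_match_fraction <- function(constants = scattering_constants) {
  -(2 * constants$b_H + constants$b_O) / (2 * (constants$b_D - constants$b_H))
}

#' Contrast specification
#'
#' A contrast is a D2O mole fraction of the hydrating water together with the
#' derived water NSLD. Water NSLD is strictly increasing in the D2O fraction.
#'
#' @param d2o_fraction D2O mole fraction in [0, 1].
#' @inheritParams water_nsld
#' @return An object of class `contrast_spec` with elements `d2o_fraction`
#'   and `water_nsld` (1e-6 Angstrom^-2).
#' @examples
#' contrast_spec(0.08)
#' @export
contrast_spec <- function(d2o_fraction, V_water = scattering_constants$V_water,
                          constants = scattering_constants) {
  stopifnot(length(d2o_fraction) == 1, is.finite(d2o_fraction),
            d2o_fraction >= 0, d2o_fraction <= 1)
  structure(
    list(d2o_fraction = d2o_fraction,
         water_nsld = water_nsld(d2o_fraction, V_water, constants)),
    class = "contrast_spec")
}

#' @export
print.contrast_spec <- function(x, ...) {
  cat(sprintf("Contrast: %.1f%% D2O, water NSLD %.3f x 1e-6 A^-2\n",
              100 * x$d2o_fraction, x$water_nsld))
  invisible(x)
}

#' Molecular volume of an n-alkanol
#'
#' Group-additive estimate V = (n-1) V_CH2 + V_CH3 + V_OH with
#' literature-typical fluid group volumes; override the group volumes (or the
#' result) when measured volumetry is available.
#'
#' @param n_carbons alkyl chain length (8-18 typical).
#' @param constants list with `V_CH2`, `V_CH3`, `V_OH`.
#' @return volume in Angstrom^3.
#' @export
alcohol_volume <- function(n_carbons, constants = scattering_constants) {
  stopifnot(all(n_carbons >= 1))
  (n_carbons - 1) * constants$V_CH2 + constants$V_CH3 + constants$V_OH
}
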