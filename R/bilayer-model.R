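#' Parametric model of a centrosymmetric fluid-phase bilayer NSLD profile
#'
#' The forward model used throughout the package for validation by parameter
#' recovery. The scattering length density across one unit cell
#' `[-D/2, D/2]` (z = 0 at the bilayer center) is the sum of
#' \itemize{
#'   \item two headgroup Gaussians at `+/- headgroup_position`,
#'   \item a methyl-trough Gaussian at the bilayer center,
#'   \item an acyl-chain plateau occupying the non-water volume fraction,
#'   \item the water contribution `water_nsld * w(z)`, where `w(z)` is a
#'     complementary-error-function step centered at
#'     `+/- interface_position` (the Gibbs dividing surface, `D_B/2`).
#' }
#' All densities are in units of 1e-6 Angstrom^-2, lengths in Angstrom.
#'
#' @param headgroup_position center of the headgroup Gaussian, Angstrom (> 0).
#' @param headgroup_sigma width of the headgroup Gaussian, Angstrom.
#' @param headgroup_amplitude peak amplitude of the headgroup Gaussian.
#' @param methyl_sigma width of the central methyl trough, Angstrom.
#' @param methyl_amplitude amplitude of the methyl trough (negative for a dip).
#' @param interface_position midpoint of the water error-function profile,
#'   equal to half the Gibbs bilayer thickness `D_B/2`, Angstrom.
#' @param interface_width Gaussian width of the water interface, Angstrom.
#' @param lattice_D lamellar repeat distance D, Angstrom.
#' @param chain_plateau NSLD of the acyl chain region.
#' @return An object of class `bilayer_model`.
#' @examples
#' m <- bilayer_model()
#' pr <- model_profile(m, contrast_spec(0.5))
#' @export
bilayer_model <- function(headgroup_position = 18.5,
                          headgroup_sigma = 3.0,
                          headgroup_amplitude = 2.5,
                          methyl_sigma = 3.0,
                          methyl_amplitude = -0.55,
                          interface_position = 22.75,
                          interface_width = 2.5,
                          lattice_D = 54.0,
                          chain_plateau = -0.3) {
  m <- list(headgroup_position = headgroup_position,
            headgroup_sigma = headgroup_sigma,
            headgroup_amplitude = headgroup_amplitude,
            methyl_sigma = methyl_sigma,
            methyl_amplitude = methyl_amplitude,
            interface_position = interface_position,
            interface_width = interface_width,
            lattice_D = lattice_D,
            chain_plateau = chain_plateau)
  validate_bilayer_model(m)
  structure(m, class = "bilayer_model")
}

validate_bilayer_model <- function(m) {
  if (!all(vapply(m, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1))))
    stop("bilayer_model: all parameters must be finite scalars")
  if (m$headgroup_sigma <= 0 || m$methyl_sigma <= 0 || m$interface_width <= 0)
    stop("bilayer_model: widths must be positive")
  if (m$lattice_D <= 0) stop("bilayer_model: lattice_D must be positive")
  if (m$headgroup_position < 0) stop("bilayer_model: headgroup_position must be >= 0")
  if (m$interface_position >= m$lattice_D / 2)
    stop("bilayer_model: interface_position must be inside the half cell")
  if (m$headgroup_position >= m$interface_position + 3 * m$interface_width)
    stop("bilayer_model: headgroups must lie within the bilayer interface")
  invisible(m)
}

#' @export
print.bilayer_model <- function(x, ...) {
  cat("Bilayer NSLD model (units: Angstrom, 1e-6 A^-2)\n")
  cat(sprintf("  D = %.2f, D_B = %.2f (interface at +/-%.2f, width %.2f)\n",
              x$lattice_D, 2 * x$interface_position, x$interface_position,
              x$interface_width))
  cat(sprintf("  headgroups at +/-%.2f (sigma %.2f, amp %.2f); methyl trough amp %.2f\n",
              x$headgroup_position, x$headgroup_sigma, x$headgroup_amplitude,
              x$methyl_amplitude))
  invisible(x)
}

#' Draw random bilayer models emulating the study sample family
#'
#' Random [bilayer_model] draws with parameters spanning fluid-phase PC
#' multilayers hydrated from water vapour at ~97-98 percent relative
#' humidity (DOPC with and without n-alkanols): repeat distance 52-56
#' Angstrom, Gibbs thickness fraction D_B / D of 0.82-0.88, headgroups
#' 3.5-5.5 Angstrom inside the Gibbs plane, interfacial widths 2-3
#' Angstrom. Used for validation by parameter recovery.
#'
#' @param n number of models.
#' @param seed integer seed (NULL = leave RNG state alone).
#' @return list of [bilayer_model] objects.
#' @export
random_bilayer_model <- function(n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) {
    D <- stats::runif(1, 52, 56)
    zW <- D * stats::runif(1, 0.41, 0.44)
    bilayer_model(
      headgroup_position = zW - stats::runif(1, 3.5, 5.5),
      headgroup_sigma = stats::runif(1, 2.5, 3.5),
      headgroup_amplitude = stats::runif(1, 2.0, 3.0),
      methyl_sigma = stats::runif(1, 2.5, 3.5),
      methyl_amplitude = stats::runif(1, -0.9, -0.4),
      interface_position = zW,
      interface_width = stats::runif(1, 2.0, 3.0),
      lattice_D = D,
      chain_plateau = -0.3)
  })
}

#' Symmetric z grid over one unit cell
#'
#' @param D lamellar repeat distance, Angstrom.
#' @param grid_spacing target grid spacing, Angstrom; the actual spacing is
#'   D / round(D / grid_spacing) so the grid hits both cell edges exactly.
#' @return numeric vector from -D/2 to D/2.
#' @keywords internal
unit_cell_grid <- function(D, grid_spacing = 0.5) {
  stopifnot(D > 0, grid_spacing > 0, grid_spacing < D)
  n <- max(8L, round(D / grid_spacing))
  if (n %% 2L == 1L) n <- n + 1L  # even count => z = 0 on the grid
  seq(-D / 2, D / 2, length.out = n + 1L)
}

#' Water volume-fraction profile of a model
#'
#' The complementary-error-function water step `w(z)`: 0 at the bilayer
#' center, 1/2 at `|z| = interface_position`, 1 in the interbilayer region.
#'
#' @param model a [bilayer_model].
#' @param z positions in Angstrom.
#' @return water volume fraction in [0, 1], even in z.
#' @export
water_fraction_profile <- function(model, z) {
  stopifnot(inherits(model, "bilayer_model"))
  0.5 * (1 + pracma::erf((abs(z) - model$interface_position) /
                           (sqrt(2) * model$interface_width)))
}

#' Evaluate the model NSLD profile at one contrast
#'
#' @param model a [bilayer_model].
#' @param contrast a [contrast_spec].
#' @param grid_spacing grid spacing in Angstrom (default 0.5, well below the
#'   resolution of a 5-6 order Fourier series).
#' @return An object of class `nsld_profile`: list with `z`, `rho`, `D`,
#'   `contrast`, and `hmax_used = NA` (a model profile is not truncated).
#' @export
model_profile <- function(model, contrast, grid_spacing = 0.5) {
  stopifnot(inherits(model, "bilayer_model"), inherits(contrast, "contrast_spec"))
  validate_bilayer_model(model)
  z <- unit_cell_grid(model$lattice_D, grid_spacing)
  w <- water_fraction_profile(model, z)
  gauss <- function(z0, sigma) exp(-(z - z0)^2 / (2 * sigma^2))
  rho <- model$chain_plateau * (1 - w) +
    model$headgroup_amplitude * (gauss(model$headgroup_position, model$headgroup_sigma) +
                                   gauss(-model$headgroup_position, model$headgroup_sigma)) +
    model$methyl_amplitude * gauss(0, model$methyl_sigma) +
    contrast$water_nsld * w
  nsld_profile(z = z, rho = rho, D = model$lattice_D, contrast = contrast,
               hmax_used = NA_integer_)
}

#' Construct an NSLD profile object
#'
#' @param z symmetric uniform grid over `[-D/2, D/2]`, Angstrom.
#' @param rho NSLD values (1e-6 Angstrom^-2) on `z`.
#' @param D lamellar repeat distance, Angstrom.
#' @param contrast the [contrast_spec] the profile corresponds to, or NULL.
#' @param hmax_used highest Fourier order used in synthesis (NA for model
#'   profiles evaluated directly).
#' @return object of class `nsld_profile`.
#' @export
nsld_profile <- function(z, rho, D, contrast = NULL, hmax_used = NA_integer_) {
  stopifnot(length(z) == length(rho), length(z) >= 3)
  dz <- diff(z)
  if (max(abs(dz - dz[1])) > 1e-8 * dz[1]) stop("nsld_profile: grid must be uniform")
  if (abs(z[1] + D / 2) > 1e-8 || abs(z[length(z)] - D / 2) > 1e-8)
    stop("nsld_profile: grid must span [-D/2, D/2]")
  structure(list(z = z, rho = rho, D = D, contrast = contrast,
                 hmax_used = hmax_used),
            class = "nsld_profile")
}

#' @export
print.nsld_profile <- function(x, ...) {
  cat(sprintf("NSLD profile: D = %.2f A, %d grid points", x$D, length(x$z)))
  if (!is.null(x$contrast))
    cat(sprintf(", %.0f%% D2O", 100 * x$contrast$d2o_fraction))
  if (!is.na(x$hmax_used)) cat(sprintf(", hmax = %d", x$hmax_used))
  cat("\n")
  invisible(x)
}
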