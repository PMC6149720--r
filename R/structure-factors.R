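#' Theoretical structure factors of an NSLD profile
#'
#' Cosine Fourier coefficients of a centrosymmetric profile over one unit
#' cell, conjugate to the synthesis used by [synthesize_profile]:
#' \deqn{F_h = \int_{-D/2}^{D/2} \rho(z) \cos(2\pi h z / D)\, dz}
#' so that `rho(z) = F_0/D + (2/D) sum_h F_h cos(2 pi h z / D)` reproduces
#' the profile as `hmax -> Inf`. `F_0` equals the profile mean times D.
#'
#' @param profile an [nsld_profile].
#' @param hmax highest diffraction order to compute (>= 1).
#' @return list with `F0` (forward value) and `F` (numeric vector of length
#'   `hmax`, signed), plus `D`.
#' @export
theoretical_structure_factors <- function(profile, hmax) {
  stopifnot(inherits(profile, "nsld_profile"), hmax >= 1)
  hmax <- as.integer(hmax)
  z <- profile$z
  D <- profile$D
  # composite Simpson quadrature: O(h^4), insensitive to the derivative
  # jump the periodic extension has at the cell boundary (trapezoid there
  # is only O(h^2))
  quad <- function(y) {
    n <- length(y) - 1L
    h <- z[2] - z[1]
    if (n %% 2L == 0L) {
      w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
      h / 3 * sum(w * y)
    } else pracma::trapz(z, y)
  }
  F0 <- quad(profile$rho)
  Fh <- vapply(seq_len(hmax), function(h)
    quad(profile$rho * cos(2 * pi * h * z / D)), numeric(1))
  list(F0 = F0, F = Fh, D = D)
}

#' Fourier synthesis of an NSLD profile from signed structure factors
#'
#' Evaluates the lamellar cosine series
#' \deqn{\rho(z) = F_{0,abs}/D + (1/k)(2/D) \sum_{h=1}^{h_{max}} F_h \cos(2\pi h z/D)}
#' on a symmetric grid over one unit cell. `F_h` are signed structure factors
#' on the relative (experimental) scale, `k` the absolute scaling factor and
#' `F0abs` the forward-scattering term that sets the profile mean.
#'
#' @param F_h numeric vector of signed structure factors for h = 1..hmax
#'   (relative scale). Must not contain NA: unsigned magnitudes must be
#'   phased first (see [assign_signs]).
#' @param D lamellar repeat distance, Angstrom.
#' @param F0abs forward scattering term; the synthesized profile mean is
#'   `F0abs / D`. Default 0 gives a zero-mean (relative) profile.
#' @param k absolute scaling factor dividing the fluctuating part (default 1).
#' @param contrast optional [contrast_spec] tag carried on the output.
#' @param grid_spacing grid spacing in Angstrom.
#' @param hmax number of orders to use (default all of `F_h`).
#' @return an [nsld_profile] with `hmax_used` set.
#' @export
synthesize_profile <- function(F_h, D, F0abs = 0, k = 1, contrast = NULL,
                               grid_spacing = 0.5, hmax = length(F_h)) {
  stopifnot(is.numeric(F_h), length(F_h) >= 1, D > 0, k != 0,
            hmax >= 1, hmax <= length(F_h))
  if (anyNA(F_h)) stop("synthesize_profile: unsigned (NA) structure factors; phase them first")
  z <- unit_cell_grid(D, grid_spacing)
  rho <- rep(F0abs / D, length(z))
  for (h in seq_len(hmax))
    rho <- rho + (1 / k) * (2 / D) * F_h[h] * cos(2 * pi * h * z / D)
  nsld_profile(z = z, rho = rho, D = D, contrast = contrast,
               hmax_used = as.integer(hmax))
}

#' Mean of a profile over the unit cell
#'
#' Trapezoid-rule cell average; for a synthesized profile this equals
#' `F0abs / D` exactly (cosine orthogonality on the uniform periodic grid).
#'
#' @param profile an [nsld_profile].
#' @return scalar mean NSLD.
#' @export
profile_mean <- function(profile) {
  pracma::trapz(profile$z, profile$rho) / profile$D
}

#' L2 distance between two profiles on a common grid
#' @param p1,p2 [nsld_profile] objects on identical grids.
#' @return scalar L2 norm of the difference (integral metric).
#' @export
profile_l2 <- function(p1, p2) {
  stopifnot(length(p1$z) == length(p2$z), max(abs(p1$z - p2$z)) < 1e-8)
  sqrt(pracma::trapz(p1$z, (p1$rho - p2$rho)^2))
}
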