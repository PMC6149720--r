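#' Area per unit cell from the Gibbs bilayer thickness
#'
#' Volumetric identity of the Gibbs construction: the bilayer volume of one
#' unit cell (two leaflets, each one lipid plus `x` alcohol molecules) fills
#' exactly the slab of thickness `D_B`, so
#' `A = 2 (V_lipid + x V_alcohol) / D_B`.
#'
#' @param D_B Gibbs bilayer thickness, Angstrom (> 0).
#' @param V_lipid lipid molecular volume, Angstrom^3.
#' @param V_alcohol alcohol molecular volume, Angstrom^3.
#' @param x alcohol:lipid mole ratio.
#' @return area per unit cell, Angstrom^2.
#' @examples
#' area_per_unit_cell(50, V_lipid = 1500)  # 60
#' @export
area_per_unit_cell <- function(D_B, V_lipid, V_alcohol = 0, x = 0) {
  stopifnot(D_B > 0, V_lipid > 0, V_alcohol >= 0, x >= 0)
  2 * (V_lipid + x * V_alcohol) / D_B
}

#' Interlamellar water count per unit cell
#'
#' `n_W = A D_W / (2 V_water)`. Convention (stated explicitly because it is
#' the field's most common factor-2 trap): the interlamellar water slab of
#' thickness `D_W` is shared by the two bilayer halves facing it, so the
#' count per lipid-unit-cell carries the factor 1/2.
#'
#' @param A area per unit cell, Angstrom^2.
#' @param D_W water layer thickness, Angstrom.
#' @param V_water water molecular volume, Angstrom^3.
#' @return water molecules per unit cell (half-slab convention).
#' @examples
#' interbilayer_waters(60, 15, 30)  # 15
#' @export
interbilayer_waters <- function(A, D_W, V_water = scattering_constants$V_water) {
  stopifnot(A > 0, D_W >= 0, V_water > 0)
  A * D_W / (2 * V_water)
}

#' Assemble and validate a per-sample bilayer structure record
#'
#' Cross-checks the structural identities at assembly time:
#' `D = D_B + D_W` (exact) and `A D_B = 2 (V_lipid + x V_alcohol)`
#' (volumetric identity, checked to `tol` relative).
#'
#' @param D lamellar repeat distance, Angstrom.
#' @param D_B Gibbs bilayer thickness, Angstrom.
#' @param D_HH head-to-head distance, Angstrom.
#' @param A area per unit cell, Angstrom^2.
#' @param n_W interlamellar waters per unit cell.
#' @param V_lipid,V_alcohol,x volumetric inputs used to derive `A` (optional;
#'   identity checked only when supplied).
#' @param sample optional sample label.
#' @param tol relative tolerance for the volumetric identity.
#' @return object of class `bilayer_structure` (also a one-row data.frame
#'   via [as.data.frame.bilayer_structure]).
#' @export
assemble_structure <- function(D, D_B, D_HH, A, n_W = NA_real_,
                               V_lipid = NULL, V_alcohol = 0, x = 0,
                               sample = NA_character_, tol = 1e-6) {
  if (D_B > D) stop("assemble_structure: identity violated: D_B > D")
  if (A <= 0) stop("assemble_structure: A must be positive")
  D_W <- water_layer(D, D_B)
  if (!is.null(V_lipid)) {
    lhs <- A * D_B
    rhs <- 2 * (V_lipid + x * V_alcohol)
    if (abs(lhs - rhs) > tol * rhs)
      stop(sprintf("assemble_structure: volumetric identity violated: A*D_B = %.4f != 2(V_l + x V_a) = %.4f",
                   lhs, rhs))
  }
  structure(list(sample = sample, D = D, D_B = D_B, D_HH = D_HH,
                 D_W = D_W, A = A, n_W = n_W, x = x),
            class = "bilayer_structure")
}

#' @export
print.bilayer_structure <- function(x, ...) {
  cat(sprintf("Bilayer structure%s (Angstrom):\n",
              if (!is.na(x$sample)) paste0(" [", x$sample, "]") else ""))
  cat(sprintf("  D = %.2f  D_B = %.2f  D_HH = %.2f  D_W = %.2f  A = %.2f A^2  n_W = %.1f\n",
              x$D, x$D_B, x$D_HH, x$D_W, x$A, x$n_W))
  invisible(x)
}

#' @export
as.data.frame.bilayer_structure <- function(x, ...) {
  data.frame(sample = x$sample, x = x$x, D = x$D, D_B = x$D_B,
             D_HH = x$D_HH, D_W = x$D_W, A = x$A, n_W = x$n_W)
}

#' Write a table of bilayer structure records as CSV
#'
#' Machine-readable per-sample results table (columns sample, x, D, D_B,
#' D_HH, D_W, A, n_W; water count uses the half-slab per-unit-cell
#' convention, see [interbilayer_waters]).
#'
#' @param records list of `bilayer_structure` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_structure_table <- function(records, path) {
  df <- do.call(rbind, lapply(records, as.data.frame))
  con <- file(path, "w")
  writeLines("# n_W convention: interlamellar waters per unit cell, half-slab (A*D_W / 2 V_water)", con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}
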