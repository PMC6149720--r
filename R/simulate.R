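#' Simulate indexed peak tables from a bilayer model
#'
#' Forward model of the reduction chain: for each contrast the model NSLD
#' profile is evaluated, its theoretical structure factors are taken, and
#' observed intensities are formed as
#' `I_h = (k F_h)^2 L_f A_c F_c` with a single global scale `k` chosen so the
#' strongest reflection across all contrasts has intensity `intensity_max`
#' (monitor-normalized counts). Two noise models are available:
#' `"counting"` adds a Gaussian approximation to Poisson statistics,
#' `sigma_I = noise_scale * sqrt(I)`, so with `intensity_max = 1` the
#' strongest peak carries a relative error of `noise_scale` and weaker
#' peaks proportionally more (equivalent to Poisson counting with the
#' strongest peak at `1 / noise_scale^2` counts); `"relative"` applies a
#' uniform relative error `sigma_I = noise_scale * I` to every peak
#' (uniformly well-measured intensities). Peak positions follow the Bragg
#' equation; orders with `h lambda / (2 D) > 1` are dropped with a warning.
#'
#' @param model a [bilayer_model].
#' @param contrasts list of [contrast_spec] objects.
#' @param hmax highest diffraction order to emit.
#' @param instrument an [instrument_config].
#' @param noise_scale noise scale (0 = noiseless).
#' @param seed integer seed making the table reproducible; NULL leaves the
#'   RNG state alone.
#' @param intensity_max intensity of the strongest reflection (default 1).
#' @param grid_spacing grid spacing for the underlying profile evaluation.
#' @param noise_model `"counting"` (default) or `"relative"`, see above.
#' @return A `peak_table`: data.frame with columns `contrast_d2o_fraction`,
#'   `order_h`, `two_theta_deg`, `intensity`, `intensity_sigma`. Attributes
#'   `truth` (list with the generator scale `k`, per-contrast signed `F_h`
#'   on the absolute scale, `F0` values, and the model) support round-trip
#'   tests.
#' @export
simulate_peak_table <- function(model, contrasts, hmax = 5,
                                instrument = instrument_config(),
                                noise_scale = 0, seed = NULL,
                                intensity_max = 1, grid_spacing = 0.25,
                                noise_model = c("counting", "relative")) {
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(model, "bilayer_model"), length(contrasts) >= 1,
            inherits(instrument, "instrument_config"),
            hmax >= 1, noise_scale >= 0, intensity_max > 0)
  if (!all(vapply(contrasts, inherits, logical(1), "contrast_spec")))
    stop("contrasts must be a list of contrast_spec objects")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  D <- model$lattice_D
  theta <- bragg_theta(seq_len(hmax), D, instrument$wavelength)
  keep <- which(!is.na(theta))
  if (length(keep) < hmax)
    warning(sprintf("dropping orders %s: Bragg angle undefined (h lambda / 2D > 1)",
                    paste(setdiff(seq_len(hmax), keep), collapse = ", ")))
  corr <- correction_factor(theta[keep], instrument)
  per_contrast <- lapply(contrasts, function(ct) {
    sf <- theoretical_structure_factors(model_profile(model, ct, grid_spacing),
                                        hmax)
    list(contrast = ct, F0 = sf$F0, F = sf$F)
  })
  # one global scale across contrasts: same sample, same monitor normalization
  peak_I <- unlist(lapply(per_contrast, function(p) p$F[keep]^2 * corr))
  k <- sqrt(intensity_max / max(peak_I))
  rows <- lapply(per_contrast, function(p) {
    I0 <- (k * p$F[keep])^2 * corr
    sig <- if (noise_model == "counting") noise_scale * sqrt(I0)
    else noise_scale * I0
    I <- pmax(0, I0 + stats::rnorm(length(I0), 0, sig))
    data.frame(contrast_d2o_fraction = p$contrast$d2o_fraction,
               order_h = keep,
               two_theta_deg = 2 * theta[keep] * 180 / pi,
               intensity = I,
               intensity_sigma = sig)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  attr(out, "truth") <- list(
    k = k, model = model,
    contrasts = contrasts,
    F = lapply(per_contrast, function(p) p$F),
    F0 = vapply(per_contrast, function(p) p$F0, numeric(1)))
  attr(out, "instrument") <- instrument
  out
}

#' Write / read peak tables as TSV
#'
#' Plain tab-separated tables with columns `contrast_d2o_fraction`,
#' `order_h`, `two_theta_deg`, `intensity`, `intensity_sigma`.
#'
#' @param x a `peak_table` data.frame.
#' @param path file path.
#' @return `read_peak_table` returns a `peak_table` data.frame.
#' @export
write_peak_table <- function(x, path) {
  utils::write.table(as.data.frame(x)[, c("contrast_d2o_fraction", "order_h",
                                          "two_theta_deg", "intensity",
                                          "intensity_sigma")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("contrast_d2o_fraction", "order_h", "two_theta_deg", "intensity")
  if (!all(need %in% names(x)))
    stop("read_peak_table: missing columns: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  if (is.null(x$intensity_sigma)) x$intensity_sigma <- NA_real_
  if (any(x$intensity < 0)) stop("read_peak_table: negative intensities")
  if (anyDuplicated(x[, c("contrast_d2o_fraction", "order_h")]))
    stop("read_peak_table: duplicate orders within a contrast")
  class(x) <- c("peak_table", "data.frame")
  x
}
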