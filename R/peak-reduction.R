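#' Rocking scan container
#'
#' An omega scan across one Bragg reflection: sample angle omega (degrees,
#' strictly increasing), detector counts, optional monitor counts and the
#' fixed detector two-theta position.
#'
#' @param omega sample angles, degrees, strictly increasing.
#' @param counts detector counts (>= 0).
#' @param monitor monitor counts for normalization (NA = pre-normalized).
#' @param detector_two_theta detector angle 2 theta, degrees.
#' @return object of class `rocking_scan`.
#' @export
rocking_scan <- function(omega, counts, monitor = NA_real_,
                         detector_two_theta = NA_real_) {
  stopifnot(length(omega) == length(counts))
  if (any(diff(omega) <= 0)) stop("rocking_scan: omega must be strictly increasing")
  if (any(counts < 0)) stop("rocking_scan: counts must be >= 0")
  structure(list(omega = omega, counts = counts, monitor = monitor,
                 detector_two_theta = detector_two_theta),
            class = "rocking_scan")
}

#' Read a rocking scan from TSV
#'
#' Columns: `omega_deg`, `counts`, optional `monitor`.
#'
#' @param path file path.
#' @param detector_two_theta detector angle, degrees (optional).
#' @return a [rocking_scan].
#' @export
read_rocking_scan <- function(path, detector_two_theta = NA_real_) {
  x <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("omega_deg", "counts") %in% names(x)))
    stop("read_rocking_scan: need columns omega_deg, counts")
  mon <- if (is.null(x$monitor)) NA_real_ else x$monitor[1]
  rocking_scan(x$omega_deg, x$counts, mon, detector_two_theta)
}

#' Fit a pseudo-Voigt mosaicity model to a rocking curve
#'
#' Least-squares fit of a shared-center Gaussian + Lorentzian sum on a
#' constant background,
#' `c(w) = b + aG exp(-(w-c)^2 / (2 sG^2)) + aL gL^2 / ((w-c)^2 + gL^2)`.
#' The Gaussian width `sigma_G` (degrees) is the mosaicity measure of the
#' aligned multilayer stack.
#'
#' @param scan a [rocking_scan] spanning the peak with at least 10 points.
#' @return list with `center`, `sigma_G`, `gamma_L`, `amp_G`, `amp_L`,
#'   `background` (all degrees/counts), `converged` (logical) and
#'   `diagnostics` (fit message, residual sd). Non-convergence is flagged,
#'   never silent.
#' @export
fit_rocking_curve <- function(scan) {
  stopifnot(inherits(scan, "rocking_scan"))
  w <- scan$omega; y <- scan$counts
  if (length(w) < 10) stop("fit_rocking_curve: need >= 10 points across the peak")
  bg0 <- min(y)
  ypk <- y - bg0
  if (max(ypk) <= 0 || sum(ypk) <= 0)
    return(list(center = NA_real_, sigma_G = NA_real_, gamma_L = NA_real_,
                amp_G = NA_real_, amp_L = NA_real_, background = bg0,
                converged = FALSE,
                diagnostics = "flat scan: no peak above background"))
  c0 <- sum(w * ypk) / sum(ypk)
  s0 <- sqrt(max(sum((w - c0)^2 * ypk) / sum(ypk), (w[2] - w[1])^2))
  # flat-scan guard: peak must rise above background noise level
  if (max(ypk) < 3 * sqrt(max(bg0, 1)) && stats::sd(y) < sqrt(max(mean(y), 1)))
    return(list(center = NA_real_, sigma_G = NA_real_, gamma_L = NA_real_,
                amp_G = NA_real_, amp_L = NA_real_, background = bg0,
                converged = FALSE,
                diagnostics = "flat scan: no significant peak"))
  dat <- data.frame(w = w, y = y)
  # unbounded fit (box constraints provoke spurious singular-gradient
  # stops in the LM implementation); widths are sign-symmetric so their
  # absolute values are reported, and degenerate results are flagged below
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + aG * exp(-(w - cc)^2 / (2 * sG^2)) +
        aL * gL^2 / ((w - cc)^2 + gL^2),
      data = dat,
      start = list(b = bg0, aG = max(ypk) * 0.8, cc = c0, sG = s0,
                   aL = max(ypk) * 0.15, gL = 2.5 * s0),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(list(center = c0, sigma_G = s0, gamma_L = NA_real_,
                amp_G = NA_real_, amp_L = NA_real_, background = bg0,
                converged = FALSE, diagnostics = conditionMessage(fit)))
  cf <- stats::coef(fit)
  ok <- is.finite(cf["sG"]) && abs(cf["sG"]) < diff(range(w)) &&
    cf["cc"] >= min(w) && cf["cc"] <= max(w)
  list(center = unname(cf["cc"]), sigma_G = abs(unname(cf["sG"])),
       gamma_L = abs(unname(cf["gL"])), amp_G = unname(cf["aG"]),
       amp_L = unname(cf["aL"]), background = unname(cf["b"]),
       converged = isTRUE(ok),
       diagnostics = if (isTRUE(ok))
         sprintf("residual sd %.4g", stats::sd(stats::resid(fit)))
       else "fit left the scan window; parameters unreliable")
}

#' Integrate one Bragg peak by Gaussian fitting
#'
#' Fits a Gaussian on a constant (or linear) background to one candidate
#' reflection and returns the analytic Gaussian area
#' `I_h = amplitude * sigma * sqrt(2 pi)`, normalized to monitor counts when
#' provided. The uncertainty is propagated from the fit covariance.
#'
#' @param angle angle axis of the segment (degrees or any linear axis).
#' @param counts counts at each angle.
#' @param monitor monitor counts (NA = already normalized; then intensities
#'   are flagged as pre-normalized in the result).
#' @param background `"constant"` or `"linear"`.
#' @return list with `I`, `sigma_I`, `center`, `sigma`, `background`,
#'   `normalized` (logical: monitor applied), `flag` (character, "" if clean).
#' @export
integrate_peak <- function(angle, counts, monitor = NA_real_,
                           background = c("constant", "linear")) {
  background <- match.arg(background)
  stopifnot(length(angle) == length(counts), length(angle) >= 6)
  o <- order(angle); angle <- angle[o]; counts <- counts[o]
  bg0 <- min(counts)
  ypk <- counts - bg0
  c0 <- if (sum(ypk) > 0) sum(angle * ypk) / sum(ypk) else mean(angle)
  s0 <- if (sum(ypk) > 0)
    sqrt(max(sum((angle - c0)^2 * ypk) / sum(ypk), diff(range(angle))^2 / 400))
  else diff(range(angle)) / 6
  dat <- data.frame(x = angle, y = counts)
  form <- if (background == "constant")
    y ~ b0 + a * exp(-(x - cc)^2 / (2 * s^2))
  else
    y ~ b0 + b1 * (x - mean(x)) + a * exp(-(x - cc)^2 / (2 * s^2))
  start <- list(b0 = bg0, a = max(ypk), cc = c0, s = s0)
  if (background == "linear") start$b1 <- 0
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(I = 0, sigma_I = NA_real_, center = c0, sigma = s0,
                background = bg0, normalized = !is.na(monitor),
                flag = paste("fit failed:", conditionMessage(fit))))
  }
  cf <- stats::coef(fit)
  a <- unname(cf["a"]); s <- abs(unname(cf["s"]))
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  area <- a * s * sqrt(2 * pi)
  # delta method on area = a s sqrt(2 pi)
  sig_area <- if (!is.null(vc) && all(c("a", "s") %in% rownames(vc))) {
    g <- c(s, a) * sqrt(2 * pi)
    sqrt(max(0, t(g) %*% vc[c("a", "s"), c("a", "s")] %*% g))
  } else NA_real_
  flag <- ""
  if (!is.na(sig_area) && a * s * sqrt(2 * pi) < 2 * sig_area) {
    flag <- "amplitude consistent with zero"
    area <- max(area, 0)
  }
  if (a <= 0) { area <- 0; flag <- "non-positive amplitude" }
  norm <- if (!is.na(monitor)) monitor else 1
  list(I = area / norm, sigma_I = sig_area / norm, center = unname(cf["cc"]),
       sigma = s, background = unname(cf["b0"]),
       normalized = !is.na(monitor), flag = flag)
}

#' Index reflections and fit the lamellar repeat distance
#'
#' Least-squares fit of the Bragg equation `2 D sin(theta_h) = h lambda`
#' across all reflections: `sin(theta_h)` is regressed on `h` through the
#' origin, giving `D = lambda / (2 slope)`. When orders are not supplied,
#' the consecutive-integer labeling `h = s, s+1, ...` (s = 1 first, per the
#' convention that the lamellar first order is always present) minimizing
#' the residual RMS is chosen; an assignment whose angular residual RMS
#' exceeds `rms_threshold` is rejected with the worst reflection named.
#'
#' @param peaks a `peak_table` data.frame (one contrast) or data.frame with
#'   `two_theta_deg` and optionally `order_h`.
#' @param wavelength neutron wavelength, Angstrom.
#' @param rms_threshold maximum acceptable residual RMS in degrees (2 theta).
#' @param max_start_order highest starting order tried when relabeling.
#' @return object of class `lattice_fit`: list with `D`, `wavelength`,
#'   `orders`, `residual_deg` (2 theta residuals), `rms_deg`.
#' @export
index_and_fit_lattice <- function(peaks, wavelength, rms_threshold = 0.1,
                                  max_start_order = 3) {
  stopifnot(is.data.frame(peaks), nrow(peaks) >= 1, wavelength > 0)
  two_theta <- peaks$two_theta_deg
  theta <- two_theta / 2 * pi / 180
  sin_t <- sin(theta)
  fit_for <- function(h) {
    slope <- sum(sin_t * h) / sum(h^2)  # regression through origin
    D <- wavelength / (2 * slope)
    pred_2t <- 2 * asin(pmin(1, h * wavelength / (2 * D))) * 180 / pi
    res <- two_theta - pred_2t
    list(D = D, res = res, rms = sqrt(mean(res^2)), orders = h)
  }
  if (!is.null(peaks$order_h) && !anyNA(peaks$order_h)) {
    f <- fit_for(peaks$order_h)
  } else {
    cands <- lapply(seq_len(max_start_order), function(s)
      fit_for(seq_len(nrow(peaks)) + s - 1L))
    f <- cands[[which.min(vapply(cands, `[[`, numeric(1), "rms"))]]
  }
  if (f$rms > rms_threshold) {
    worst <- which.max(abs(f$res))
    stop(sprintf(paste0("index_and_fit_lattice: residual RMS %.4f deg exceeds ",
                        "threshold %.3f; worst reflection h = %d at 2theta = %.3f deg ",
                        "(residual %.4f deg). Check order assignment."),
                 f$rms, rms_threshold, f$orders[worst], two_theta[worst],
                 f$res[worst]))
  }
  structure(list(D = f$D, wavelength = wavelength, orders = f$orders,
                 residual_deg = f$res, rms_deg = f$rms),
            class = "lattice_fit")
}

#' @export
print.lattice_fit <- function(x, ...) {
  cat(sprintf("Lattice fit: D = %.4f A (lambda = %.4f A, %d reflections, RMS %.2g deg)\n",
              x$D, x$wavelength, length(x$orders), x$rms_deg))
  invisible(x)
}

#' Extrapolate the fully hydrated D-spacing from hydration kinetics
#'
#' Fits the saturating exponential `D(t) = D_inf - dD exp(-t / tau)` to a
#' time series of repeat distances measured while the sample takes up water
#' (saturation is typically reached within a few hundred minutes). A
#' decreasing series (approach from above) is handled by a negative `dD`.
#'
#' @param times time points, minutes (>= 4 values).
#' @param d_spacings measured D, Angstrom.
#' @param conf_level confidence level for the interval on `D_inf`.
#' @return list with `D_full`, `ci` (length-2), `dD`, `tau`, `converged`,
#'   `flag` ("" if clean). A non-saturating series returns the last value
#'   with a warning flag rather than failing.
#' @export
extrapolate_full_hydration <- function(times, d_spacings, conf_level = 0.95) {
  stopifnot(length(times) == length(d_spacings), length(times) >= 4)
  o <- order(times); times <- times[o]; d <- d_spacings[o]
  last <- d[length(d)]
  if (stats::sd(d) < 1e-12)
    return(list(D_full = last, ci = c(last, last), dD = 0, tau = NA_real_,
                converged = TRUE, flag = "constant series"))
  dD0 <- last - d[1]
  tau0 <- max(diff(range(times)) / 3, 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(d ~ Dinf - dD * exp(-times / tau),
                      start = list(Dinf = last, dD = dD0, tau = tau0),
                      lower = c(-Inf, -Inf, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    warning("extrapolate_full_hydration: fit did not converge; returning last value")
    return(list(D_full = last, ci = c(NA_real_, NA_real_), dD = NA_real_,
                tau = NA_real_, converged = FALSE,
                flag = paste("non-convergence:", conditionMessage(fit))))
  }
  cf <- stats::coef(fit)
  flag <- ""
  if (cf[["tau"]] > 2 * max(times)) {
    flag <- "series not saturating within the measured window"
    warning("extrapolate_full_hydration: ", flag)
  }
  se <- tryCatch(sqrt(stats::vcov(fit)["Dinf", "Dinf"]), error = function(e) NA_real_)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(D_full = unname(cf["Dinf"]),
       ci = unname(cf["Dinf"]) + c(-1, 1) * zq * se,
       dD = unname(cf["dD"]), tau = unname(cf["tau"]),
       converged = TRUE, flag = flag)
}
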