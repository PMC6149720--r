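test_that("water NSLD follows scattering-length mixing and nulls near 8% D2O", {
  fr <- seq(0, 1, by = 0.1)
  nsld <- water_nsld(fr)
  expect_true(all(diff(nsld) > 0))                  # strictly increasing
  f0 <- contrast_match_fraction()
  expect_gt(f0, 0.07); expect_lt(f0, 0.09)          # the 8% D2O null
  expect_equal(water_nsld(f0), 0, tolerance = 1e-12)
  # endpoints from first principles: b(H2O) = 2 b_H + b_O over V_w
  k <- scattering_constants
  expect_equal(water_nsld(0), 10 * (2 * k$b_H + k$b_O) / k$V_water)
  expect_equal(water_nsld(1), 10 * (2 * k$b_D + k$b_O) / k$V_water)
})

test_that("model profiles are centrosymmetric and the null model is flat", {
  null_model <- bilayer_model(headgroup_amplitude = 0, methyl_amplitude = 0,
                              chain_plateau = 0)
  ct0 <- contrast_spec(contrast_match_fraction())   # water NSLD ~ 0
  p <- model_profile(null_model, ct0)
  expect_lt(max(abs(p$rho)), 1e-12)
  m <- reference_model()
  for (ct in study_contrasts()) {
    pr <- model_profile(m, ct, 0.25)
    expect_identical(pr$rho, rev(pr$rho))           # exactly even
  }
})

test_that("contrast dependence of the profile is the water term exactly", {
  m <- reference_model()
  cts <- study_contrasts()
  profs <- lapply(cts, model_profile, model = m, grid_spacing = 0.25)
  w_oracle <- 0.5 * (1 + pracma::erf((abs(profs[[1]]$z) - m$interface_position) /
                                       (sqrt(2) * m$interface_width)))
  for (i in 1:2) for (j in (i + 1):3) {
    dn <- cts[[j]]$water_nsld - cts[[i]]$water_nsld
    expect_equal((profs[[j]]$rho - profs[[i]]$rho) / dn, w_oracle,
                 tolerance = 1e-10)
  }
})

test_that("non-physical models are rejected", {
  expect_error(bilayer_model(headgroup_sigma = -1), "widths")
  expect_error(bilayer_model(interface_position = 40, lattice_D = 54), "half cell")
  expect_error(bilayer_model(headgroup_position = 35), "interface")
})

test_that("water term integrates to the geometric water volume", {
  m <- reference_model()
  z <- seq(0, m$lattice_D / 2, by = 0.01)
  w <- 0.5 * (1 + pracma::erf((z - m$interface_position) /
                                (sqrt(2) * m$interface_width)))
  A <- 60
  vol_geom <- A * (m$lattice_D / 2 - m$interface_position)   # per monolayer
  # 2% slack: the erf tail is clipped at the cell edge in these systems
  expect_equal(A * pracma::trapz(z, w), vol_geom, tolerance = 0.02)
})

test_that("structure factors obey orthogonality and refine under the grid", {
  D <- 54
  z <- seq(-D / 2, D / 2, length.out = 109)
  flat <- nsld_profile(z, rep(2.5, length(z)), D)
  sf <- theoretical_structure_factors(flat, 4)
  expect_equal(sf$F0, 2.5 * D, tolerance = 1e-10)
  expect_lt(max(abs(sf$F)), 1e-10)
  cosine <- nsld_profile(z, 3 * cos(2 * pi * z / D), D)
  sfc <- theoretical_structure_factors(cosine, 4)
  expect_equal(sfc$F[1], 3 * D / 2, tolerance = 1e-6)
  expect_lt(max(abs(sfc$F[2:4])), 1e-8)
  # refinement oracle: halving the grid spacing changes F_h by < 1e-6 rel.
  m <- reference_model()
  ct <- study_contrasts()[[3]]
  f1 <- theoretical_structure_factors(model_profile(m, ct, 0.125), 6)
  f2 <- theoretical_structure_factors(model_profile(m, ct, 0.0625), 6)
  expect_equal(f1$F, f2$F, tolerance = 1e-6)
})

test_that("simulated peak tables are reproducible and invert exactly", {
  m <- reference_model()
  t1 <- simulate_peak_table(m, study_contrasts(), noise_scale = 0.05, seed = 7)
  t2 <- simulate_peak_table(m, study_contrasts(), noise_scale = 0.05, seed = 7)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # noiseless round trip through the corrections recovers k |F_h| exactly
  t0 <- simulate_peak_table(m, study_contrasts(), noise_scale = 0, seed = 1)
  tr <- attr(t0, "truth")
  inst <- attr(t0, "instrument")
  theta <- t0$two_theta_deg / 2 * pi / 180
  fm <- structure_factor_magnitude(
    t0$intensity, lorentz_factor(theta),
    absorption_factor(theta, inst$mu, inst$sample_thickness),
    flux_factor(theta, inst$sample_length, inst$beam_sigma))
  expect_equal(fm$F_mag, tr$k * abs(unlist(tr$F)), tolerance = 1e-12)
})

test_that("simulated peak angles follow the Bragg equation", {
  m <- bilayer_model(lattice_D = 50, interface_position = 21)
  tab <- simulate_peak_table(m, study_contrasts()[1], hmax = 5)
  lambda <- attr(tab, "instrument")$wavelength
  expect_equal(lambda, 4.5707)
  expect_equal(tab$two_theta_deg,
               2 * asin((1:5) * lambda / (2 * 50)) * 180 / pi,
               tolerance = 1e-12)
  # inverse map: recomputing D from each angle returns 50 exactly
  expect_equal((1:5) * lambda / (2 * sin(tab$two_theta_deg / 2 * pi / 180)),
               rep(50, 5), tolerance = 1e-10)
})

test_that("reflections beyond the Bragg limit are dropped with a warning", {
  m <- bilayer_model(lattice_D = 54, interface_position = 22.75)
  inst <- instrument_config(wavelength = 15)   # h lambda/2D > 1 for h >= 8
  expect_warning(
    tab <- simulate_peak_table(m, study_contrasts()[1], hmax = 8,
                               instrument = inst),
    "Bragg angle undefined")
  expect_true(all(tab$order_h <= floor(2 * 54 / 15)))
})

test_that("synthetic frames hit prescribed order parameters", {
  bonds <- data.frame(from = "C1A", to = "C2A")
  aligned <- synthetic_frames(500, order_target = 1, seed = 1)
  expect_equal(order_parameter(aligned, bonds)$P2, 1)
  planar <- synthetic_frames(500, order_target = -0.5, seed = 2)
  expect_equal(order_parameter(planar, bonds)$P2, -0.5)
  iso <- synthetic_frames(10000, order_target = 0, seed = 3)
  op <- order_parameter(iso, bonds)
  expect_lt(abs(op$P2), 3 * op$stderr)
  expect_error(synthetic_frames(10, order_target = 2), "order_target")
})
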