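test_that("Fourier synthesis honors the DC term and symmetry", {
  p0 <- synthesize_profile(rep(0, 4), D = 54, F0abs = 27)
  expect_equal(unique(p0$rho), 0.5)                  # constant F0abs / D
  p1 <- synthesize_profile(c(10, 0, 0), D = 54, F0abs = 0)
  expect_equal(p1$rho, (2 / 54) * 10 * cos(2 * pi * p1$z / 54),
               tolerance = 1e-12)
  m <- reference_model()
  sf <- theoretical_structure_factors(model_profile(m, study_contrasts()[[2]]), 6)
  ps <- synthesize_profile(sf$F, 54, F0abs = sf$F0)
  expect_identical(ps$rho, rev(ps$rho))              # exactly even
  expect_equal(profile_mean(ps), sf$F0 / 54, tolerance = 1e-10 * abs(sf$F0 / 54))
  expect_error(synthesize_profile(c(1, NA), D = 54), "unsigned")
})

test_that("truncation error decreases monotonically with hmax", {
  m <- reference_model()
  ct <- study_contrasts()[[1]]
  pm <- model_profile(m, ct, 0.25)
  sf <- theoretical_structure_factors(pm, 8)
  errs <- vapply(3:8, function(hm)
    profile_l2(synthesize_profile(sf$F, m$lattice_D, F0abs = sf$F0,
                                  grid_spacing = 0.25, hmax = hm), pm),
    numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("head-to-head distance finds the headgroup maxima", {
  m <- bilayer_model(headgroup_position = 18)
  ct <- contrast_spec(contrast_match_fraction())
  pr <- model_profile(m, ct, 0.25)
  hh <- head_to_head(pr)
  expect_equal(hh$D_HH, 36, tolerance = 0.25)        # within a grid spacing
  expect_equal(hh$z_max[1], -hh$z_max[2], tolerance = 1e-9)  # mirror images
  # truncation study: positions converge towards the model value
  sf <- theoretical_structure_factors(pr, 6)
  d4 <- head_to_head(synthesize_profile(sf$F, m$lattice_D, F0abs = sf$F0,
                                        grid_spacing = 0.25, hmax = 4))$D_HH
  d6 <- head_to_head(synthesize_profile(sf$F, m$lattice_D, F0abs = sf$F0,
                                        grid_spacing = 0.25, hmax = 6))$D_HH
  expect_lte(abs(d6 - hh$D_HH), abs(d4 - hh$D_HH) + 0.05)
  # a profile with no off-center maxima is rejected
  flat <- nsld_profile(pr$z, -cos(2 * pi * pr$z / m$lattice_D), m$lattice_D)
  expect_error(head_to_head(flat), "boundary|maxima")
})

test_that("water distribution recovers the generator water profile", {
  m <- reference_model()
  profs <- lapply(study_contrasts(), model_profile, model = m,
                  grid_spacing = 0.25)
  wd <- water_distribution(profs)
  w_true <- 0.5 * (1 + pracma::erf((abs(wd$z) - m$interface_position) /
                                     (sqrt(2) * m$interface_width)))
  # normalize the oracle the same way (these cramped cells have no fully
  # saturated plateau; the op normalizes the outer-10% mean to 1)
  w_true <- w_true / mean(w_true[abs(wd$z) > 0.45 * m$lattice_D])
  expect_lt(max(abs(wd$w - w_true)), 0.02)           # 2% pointwise
  # any single pair gives the same distribution (noiseless consistency)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    wp <- water_distribution(profs[pair])
    expect_lt(max(abs(wp$w - wd$w)), 0.02)
  }
  expect_error(
    suppressWarnings(water_distribution(list(profs[[2]], profs[[2]]))),
    "no contrast pair")
})

test_that("Gibbs interface fitting is exact for steps and width-invariant", {
  D <- 54
  z <- seq(-D / 2, D / 2, length.out = 217)
  step <- as.numeric(abs(z) >= 21.5)
  wp <- structure(list(z = z, w = step, plateau_raw = 1, D = D,
                       pairs = data.frame(), hmax = NA_integer_),
                  class = "water_profile")
  g <- gibbs_interface(wp)
  expect_equal(g$D_B, 43, tolerance = 0.15)
  expect_equal(g$D_B_integral, 43, tolerance = 0.15)
  # widening the interface at fixed midpoint leaves D_B unchanged
  for (wdt in c(1.5, 2.5, 3.5)) {
    m <- bilayer_model(interface_width = wdt)
    wd <- water_distribution(lapply(study_contrasts(), model_profile,
                                    model = m, grid_spacing = 0.25))
    expect_equal(gibbs_interface(wd)$D_B, 2 * m$interface_position,
                 tolerance = 0.02 * 2 * m$interface_position)
  }
})

test_that("water layer closes the lattice identity", {
  expect_equal(water_layer(60, 46), 14)
  expect_equal(water_layer(60, 60), 0)
  expect_error(water_layer(50, 55), "exceeds")
  m <- reference_model()
  sr <- simulate_and_reduce(m, seed = 1)
  s <- sr$res$structure
  expect_identical(s$D, s$D_B + s$D_W)               # exact by construction
  expect_equal(s$D_W, m$lattice_D - 2 * m$interface_position, tolerance = 0.5)
})

test_that("full noiseless chain recovers the generator structure", {
  models <- random_bilayer_model(5, seed = 77)
  for (m in models) {
    sr <- simulate_and_reduce(m, noise_scale = 0, seed = 1)
    expect_equal(sr$res$structure$D, m$lattice_D, tolerance = 1e-6)
    expect_equal(sr$res$structure$D_B, 2 * m$interface_position,
                 tolerance = 0.02 * 2 * m$interface_position)
    hh_true <- head_to_head(model_profile(m, study_contrasts()[[1]], 0.1))$D_HH
    expect_equal(sr$res$structure$D_HH, hh_true, tolerance = 0.5)
  }
})

test_that("profile CSV output round-trips through the sidecar", {
  m <- reference_model()
  pr <- model_profile(m, study_contrasts()[[1]])
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_profile_csv(pr, csv, sidecar = js)
  back <- utils::read.csv(csv)
  expect_equal(back$nsld, pr$rho, tolerance = 1e-9)
  meta <- jsonlite::read_json(js)
  expect_equal(meta$D, m$lattice_D)
  unlink(c(csv, js))
})
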