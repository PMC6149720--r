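test_that("rocking-curve fits recover an injected mosaic width", {
  set.seed(11)
  om <- seq(-0.5, 0.5, by = 0.01)
  # generate-and-refit at the instrument-typical width scale (0.076 deg)
  for (sg in c(0.05, 0.076, 0.12)) {
    counts <- 40 + 1200 * exp(-om^2 / (2 * sg^2)) + rnorm(length(om), 0, 4)
    fit <- fit_rocking_curve(rocking_scan(om, pmax(counts, 0)))
    expect_true(fit$converged)
    expect_equal(fit$sigma_G, sg, tolerance = 0.05)
    # symmetric peak: center agrees with the background-subtracted
    # center of mass
    expect_lt(abs(fit$center), 0.01)
  }
})

test_that("flat rocking scans are flagged, not silently fitted", {
  om <- seq(-1, 1, by = 0.05)
  fit <- fit_rocking_curve(rocking_scan(om, rep(25, length(om))))
  expect_false(fit$converged)
  expect_match(fit$diagnostics, "flat")
  expect_error(fit_rocking_curve(rocking_scan(om[1:5], rep(1, 5))), ">= 10")
})

test_that("peak integration matches a quadrature oracle and normalizes", {
  set.seed(3)
  x <- seq(-1, 1, by = 0.02)
  s <- 0.12; area <- 100; bg <- 5
  y <- bg + area / (s * sqrt(2 * pi)) * exp(-x^2 / (2 * s^2)) +
    rnorm(length(x), 0, 0.8)
  # oracle: numeric quadrature of the background-subtracted curve
  oracle <- pracma::trapz(x, y - bg)
  ip <- integrate_peak(x, pmax(y, 0))
  expect_equal(ip$I, oracle, tolerance = 0.01)
  expect_equal(ip$I, area, tolerance = 0.01)
  expect_true(is.finite(ip$sigma_I))
  # doubling counts and monitor together leaves I unchanged
  ip2 <- integrate_peak(x, 2 * pmax(y, 0), monitor = 2)
  expect_equal(ip2$I, ip$I, tolerance = 1e-6)
  expect_true(ip2$normalized)
  # invariance under angle-axis shift
  ip3 <- integrate_peak(x + 3.7, pmax(y, 0))
  expect_equal(ip3$I, ip$I, tolerance = 1e-8)
})

test_that("zero-amplitude segments integrate to zero with a flag", {
  set.seed(4)
  x <- seq(-1, 1, by = 0.05)
  y <- 10 + rnorm(length(x), 0, 0.5)
  ip <- integrate_peak(x, pmax(y, 0))
  expect_lt(abs(ip$I), 3)
  expect_true(nzchar(ip$flag))
})

test_that("lattice fitting solves the Bragg equation", {
  lambda <- 4.5707
  # single reflection: closed form D = lambda / (2 sin theta)
  th1 <- 2 * asin(lambda / (2 * 61)) * 180 / pi
  f1 <- index_and_fit_lattice(data.frame(two_theta_deg = th1, order_h = 1),
                              lambda)
  expect_equal(f1$D, 61, tolerance = 1e-10)
  # five noiseless synthetic orders at D = 50
  m <- bilayer_model(lattice_D = 50, interface_position = 21)
  tab <- simulate_peak_table(m, study_contrasts()[1], hmax = 5)
  f5 <- index_and_fit_lattice(tab, lambda)
  expect_equal(f5$D, 50, tolerance = 1e-9)
  expect_lt(f5$rms_deg, 1e-9)
  # automatic consecutive assignment starting at h = 1
  fauto <- index_and_fit_lattice(data.frame(two_theta_deg = tab$two_theta_deg),
                                 lambda)
  expect_identical(fauto$orders, 1:5)
  expect_equal(fauto$D, 50, tolerance = 1e-9)
  # labels shifted by one violate the Bragg ladder and are rejected
  expect_error(
    index_and_fit_lattice(data.frame(two_theta_deg = tab$two_theta_deg,
                                     order_h = 2:6), lambda),
    "residual RMS")
})

test_that("full-hydration extrapolation recovers the asymptote", {
  expect_equal(extrapolate_full_hydration(c(0, 50, 150, 400),
                                          rep(63.2, 4))$D_full, 63.2)
  set.seed(21)
  tt <- seq(0, 400, by = 10)
  dd <- 64 - 10 * exp(-tt / 80) + rnorm(length(tt), 0, 0.1)
  fit <- extrapolate_full_hydration(tt, dd)
  expect_true(fit$converged)
  expect_equal(fit$D_full, 64, tolerance = 0.3)
  expect_true(fit$ci[1] < 64 && fit$ci[2] > 63)
  # approach from above: negative amplitude, same asymptote
  dd2 <- 64 + 6 * exp(-tt / 80) + rnorm(length(tt), 0, 0.1)
  fit2 <- extrapolate_full_hydration(tt, dd2)
  expect_equal(fit2$D_full, 64, tolerance = 0.3)
  expect_lt(fit2$dD, 0)
})

test_that("scan and peak-table text round trips preserve data", {
  tmp <- tempfile(fileext = ".tsv")
  m <- reference_model()
  tab <- simulate_peak_table(m, study_contrasts(), noise_scale = 0.02, seed = 5)
  write_peak_table(tab, tmp)
  back <- read_peak_table(tmp)
  expect_equal(back$intensity, tab$intensity, tolerance = 1e-9)
  expect_equal(back$order_h, tab$order_h)
  writeLines(c("omega_deg\tcounts\tmonitor",
               sprintf("%.3f\t%d\t1000", seq(-0.5, 0.5, 0.1), 10:20)), tmp)
  sc <- read_rocking_scan(tmp)
  expect_s3_class(sc, "rocking_scan")
  expect_equal(sc$monitor, 1000)
  unlink(tmp)
})
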