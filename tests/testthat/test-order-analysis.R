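test_that("P2 attains its exact endpoints and stays in range", {
  bonds <- data.frame(from = "C1A", to = "C2A")
  expect_equal(order_parameter(synthetic_frames(200, order_target = 1,
                                                seed = 1), bonds)$P2, 1)
  expect_equal(order_parameter(synthetic_frames(200, order_target = -0.5,
                                                seed = 2), bonds)$P2, -0.5)
  for (tgt in c(-0.3, 0, 0.4, 0.8)) {
    op <- order_parameter(synthetic_frames(4000, order_target = tgt,
                                           seed = 10 + round(10 * tgt)), bonds)
    expect_gte(op$P2, -0.5); expect_lte(op$P2, 1)
    expect_lt(abs(op$P2 - tgt), 4 * op$stderr)
  }
  expect_error(order_parameter(synthetic_frames(10, seed = 1),
                               data.frame(from = "XX", to = "C2A")),
               "not present")
})

test_that("density profiles conserve counts and match quantile oracles", {
  # uniform slab between |z| = 3 and 12: inner-90% span [3.45, 11.55]
  set.seed(31)
  n <- 4000
  zs <- sample(c(-1, 1), n, TRUE) * runif(n, 3, 12)
  fr <- particle_frame(cbind(runif(n, 0, 50), runif(n, 0, 50), zs),
                       rep("D2A", n), seq_len(n), c(50, 50, 40))
  dp <- density_profile(list(fr), "D2A", bin_width = 0.5,
                        center_labels = "D2A")
  expect_equal(sum(dp$counts), dp$n)                 # count conservation
  expect_gt(dp$span90[1], 3.2); expect_lt(dp$span90[1], 3.7)
  expect_gt(dp$span90[2], 11.3); expect_lt(dp$span90[2], 11.8)
  # Gaussian-placed beads match Gaussian quantiles within binning error
  zg <- rnorm(n, 0, 2.5)
  frg <- particle_frame(cbind(runif(n, 0, 50), runif(n, 0, 50), zg),
                        rep("PO4", n), seq_len(n), c(50, 50, 40))
  dpg <- density_profile(list(frg), "PO4", bin_width = 0.5,
                         center_labels = "PO4")
  half_q <- qnorm(c(0.525, 0.975), 0, 2.5)           # |z| quantiles
  expect_equal(dpg$span90, half_q, tolerance = 0.15)
  # single particle lands in exactly one bin
  fr1 <- particle_frame(cbind(0, 0, 5), "PO4", 1L, c(10, 10, 20))
  dp1 <- density_profile(list(fr1), "PO4", bin_width = 1,
                         center_labels = NULL)
  expect_equal(sum(dp1$counts > 0), 1)
  expect_error(density_profile(list(fr1), "ZZZ", 1), "empty selection")
})

test_that("phosphate-to-phosphate thickness is the leaflet mean gap", {
  n <- 40
  fr <- particle_frame(cbind(runif(n), runif(n), rep(c(19, -19), n / 2)),
                       rep("PO4", n), seq_len(n), c(50, 50, 80))
  expect_equal(bilayer_thickness_pp(list(fr))$D_PP, 38)
  # symmetric zero-mean noise leaves D_PP unchanged in expectation
  set.seed(17)
  dpp <- replicate(200, {
    z <- rep(c(19, -19), n / 2) + rnorm(n, 0, 1.5)
    bilayer_thickness_pp(list(particle_frame(
      cbind(runif(n), runif(n), z), rep("PO4", n), seq_len(n),
      c(50, 50, 80))))$D_PP
  })
  expect_lt(abs(mean(dpp) - 38), 3 * sd(dpp) / sqrt(length(dpp)))
  one <- particle_frame(cbind(runif(4), runif(4), rep(5, 4)),
                        rep("PO4", 4), 1:4, c(10, 10, 20))
  expect_error(bilayer_thickness_pp(list(one)), "leaflet")
})

test_that("lateral RDF is flat for Poisson planes and peaked for lattices", {
  pois <- synthetic_poisson_frame(400, n_frames = 15, seed = 9)
  g <- lateral_rdf(pois, bin_width = 1, r_max = 40)
  expect_lt(max(abs(g$g - 1) / g$g_sd), 5)
  # density-weighted neighbor count: integral of g rho 2 pi r dr = N - 1
  rho <- 399 / (100 * 100)
  neighbors <- sum(g$g * rho * 2 * pi * g$r * 1)
  expect_equal(neighbors, pi * 40^2 * rho, tolerance = 0.05)
  hx <- synthetic_hex_frame(a = 8, nx = 12, ny = 12)
  gh <- lateral_rdf(list(hx), bin_width = 0.5, r_max = 20)
  first_peak <- gh$r[which.max(gh$g * (gh$r < 12))]
  expect_lt(abs(first_peak - 8), 0.5 + 0.26)         # within one bin
  expect_error(lateral_rdf(pois, r_max = 80), "r_max")
  single <- particle_frame(cbind(1, 1, 5), "PO4", 1L, c(10, 10, 10))
  expect_error(lateral_rdf(list(single)), "fewer than 2")
})

test_that("group distances recover prescribed offsets per leaflet", {
  n <- 20
  mk <- function(zA, zB) particle_frame(
    rbind(cbind(runif(n), runif(n), rep(c(zA, -zA), n / 2)),
          cbind(runif(n), runif(n), rep(c(zB, -zB), n / 2))),
    c(rep("PO4", n), rep("GL1", n)), c(1:n, 1:n), c(50, 50, 80))
  expect_equal(group_distance(list(mk(19, 15)), "PO4", "GL1")$distance, 4)
  expect_equal(group_distance(list(mk(17, 17)), "PO4", "GL1")$distance, 0)
  # sign convention: negative when A sits closer to the center than B
  expect_equal(group_distance(list(mk(15, 19)), "PO4", "GL1")$distance, -4)
  expect_error(group_distance(list(mk(19, 15)), "PO4", "OH"), "empty group")
})

test_that("observables are invariant to rigid translation and frame order", {
  frames <- synthetic_frames(300, order_target = 0.4, n_frames = 3, seed = 6)
  bonds <- data.frame(from = "C1A", to = "C2A")
  shift <- function(fr, dz) {
    fr$z <- fr$z + dz
    fr
  }
  shifted <- lapply(frames, shift, dz = 7.3)
  expect_equal(order_parameter(shifted, bonds)$P2,
               order_parameter(frames, bonds)$P2, tolerance = 1e-12)
  expect_equal(order_parameter(rev(frames), bonds)$P2,
               order_parameter(frames, bonds)$P2, tolerance = 1e-12)
  pois <- synthetic_poisson_frame(150, n_frames = 2, seed = 3)
  g1 <- lateral_rdf(pois, bin_width = 2, r_max = 30)
  g2 <- lateral_rdf(rev(pois), bin_width = 2, r_max = 30)
  expect_equal(g1$g, g2$g, tolerance = 1e-12)
})

test_that("frame text formats round-trip", {
  frames <- synthetic_frames(25, order_target = 0.5, n_frames = 2, seed = 4)
  f <- tempfile(fileext = ".xyz")
  write_frames_xyz(frames, f)
  back <- read_frames_xyz(f)
  expect_length(back, 2)
  expect_equal(back[[1]]$z, frames[[1]]$z, tolerance = 1e-5)
  expect_identical(back[[2]]$label, frames[[2]]$label)
  expect_equal(attr(back[[1]], "box"), attr(frames[[1]], "box"),
               tolerance = 1e-5)
  unlink(f)
  # GRO fixed-width reader (nm -> Angstrom)
  g <- tempfile(fileext = ".gro")
  writeLines(c("bilayer", "2",
               "    1DOPC   PO4    1   1.500   2.000   3.250",
               "    1DOPC   GL1    2   1.500   2.000   2.850",
               "   5.00000   5.00000   8.00000"), g)
  fr <- read_gro(g)
  expect_equal(fr$z, c(32.5, 28.5))
  expect_identical(fr$label, c("PO4", "GL1"))
  expect_equal(attr(fr, "box"), c(50, 50, 80))
  unlink(g)
})
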