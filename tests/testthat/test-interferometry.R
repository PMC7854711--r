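test_that("extract_phase recovers a flat phase from an unperturbed carrier", {
  img <- fringe_image(nr = 96, nc = 96)
  ph <- extract_phase(scalar_field(img, "intensity", 1))
  flat <- phase_difference(ph, scalar_field(matrix(0, 96, 96), "phase_rad", 1))
  expect_lt(diff(range(flat$grid)), 1e-6)
})

test_that("extract_phase recovers a known Gaussian phase bump", {
  # bump wide enough that its spectrum sits well inside the Hann window
  bump <- gauss_bump(256, 256, amplitude = 4.6, sd_row = 24)
  img <- fringe_image(bump, nr = 256, nc = 256)
  ph <- extract_phase(scalar_field(img, "intensity", 1))
  ref <- extract_phase(scalar_field(fringe_image(nr = 256, nc = 256),
                                    "intensity", 1))
  dphi <- phase_difference(ph, ref)
  expect_equal(max(dphi$grid), 4.6, tolerance = 0.02)
})

test_that("extract_phase rejects images with no carrier and is scale invariant", {
  set.seed(11)
  noise <- matrix(rnorm(64 * 64, 100, 5), 64, 64)
  expect_error(extract_phase(scalar_field(noise, "intensity", 1)), "no-carrier")

  img <- fringe_image(gauss_bump(96, 96, 2, 10), nr = 96, nc = 96)
  ph1 <- extract_phase(scalar_field(img, "intensity", 1))
  ph2 <- extract_phase(scalar_field(3.7 * img, "intensity", 1))
  expect_lt(max(abs(ph1$grid - ph2$grid)), 1e-6)
})

test_that("phase_difference subtracts, removes tilt, and checks shapes", {
  z <- matrix(0, 64, 64)
  bump <- gauss_bump(64, 64, 2, 6, row0 = 40)
  pf <- function(m) scalar_field(m, "phase_rad", 1)
  expect_equal(phase_difference(pf(bump), pf(bump))$grid, z, tolerance = 1e-12)
  d <- phase_difference(pf(bump + 5), pf(z), detrend = FALSE)
  expect_equal(d$grid, bump + 5, tolerance = 1e-12)

  tilt <- outer(seq_len(64) * 0.01, rep(1, 64)) +
    outer(rep(1, 64), seq_len(64) * 0.02) + 0.3
  d2 <- phase_difference(pf(bump + tilt), pf(z))
  expect_lt(max(abs(d2$grid - bump)), 1e-3)

  expect_error(phase_difference(pf(z), pf(matrix(0, 64, 32))), "incompatible")
})

test_that("phase, index and density conversions are the stated linear maps", {
  pf <- scalar_field(matrix(2 * pi, 16, 16), "phase_rad", 1)
  dn <- phase_to_index(pf, 400, 2)
  expect_equal(dn$grid[1, 1], 2e-4, tolerance = 1e-12)
  expect_equal(dn$quantity, "delta_n")
  # halving the path doubles delta-n
  expect_equal(phase_to_index(pf, 400, 1)$grid, 2 * dn$grid, tolerance = 1e-12)
  z <- phase_to_index(scalar_field(matrix(0, 16, 16), "phase_rad", 1), 400, 2)
  expect_true(all(z$grid == 0))
  expect_error(phase_to_index(pf, -400, 2), "invalid parameter")

  dn2 <- scalar_field(matrix(3.22e-4, 16, 16), "delta_n", 1)
  expect_equal(index_to_density(dn2)$grid[1, 1], 1e-3, tolerance = 1e-12)
  # linearity
  a <- scalar_field(matrix(runif(256), 16, 16), "delta_n", 1)
  b <- scalar_field(matrix(runif(256), 16, 16), "delta_n", 1)
  ab <- scalar_field(a$grid + b$grid, "delta_n", 1)
  expect_equal(index_to_density(ab)$grid,
               index_to_density(a)$grid + index_to_density(b)$grid,
               tolerance = 1e-12)
})

test_that("Tait conversion is monotone, zero at equilibrium, and linear-acoustic at small signal", {
  eos <- tait_eos()
  cs2 <- eos$k0_Pa / (eos$rho0_gcm3 * 1000) # cs^2 in SI
  mk <- function(x) scalar_field(matrix(x, 16, 16), "delta_rho_gcm3", 1)
  expect_equal(density_to_pressure(mk(0), eos)$grid[1, 1], 0, tolerance = 1e-15)
  # ~1 MPa at delta-rho = 4.55e-4 g/cm^3 (small-signal oracle P = cs^2 drho)
  p1 <- density_to_pressure(mk(4.55e-4), eos)$grid[1, 1]
  expect_equal(p1, cs2 * 4.55e-4 * 1000 / 1e6, tolerance = 0.01)
  expect_equal(p1, 1.0, tolerance = 0.01)
  # monotone in delta-rho
  dr <- seq(-2e-3, 2e-3, length.out = 41)
  pp <- vapply(dr, function(x) density_to_pressure(mk(x), eos)$grid[1, 1],
               numeric(1))
  expect_true(all(diff(pp) > 0))
  # small-signal limit within 1% for |drho|/rho0 < 1e-3
  for (x in c(-9e-4, -1e-4, 1e-5, 5e-4, 9.9e-4) * eos$rho0_gcm3) {
    expect_equal(density_to_pressure(mk(x), eos)$grid[1, 1],
                 cs2 * x * 1000 / 1e6, tolerance = 0.01)
  }
  expect_error(density_to_pressure(mk(-1), eos), "unphysical density")
})

test_that("pressure_map inverts a rendered interferogram (round trip)", {
  cfg <- sim_config(seed = 5)
  fld <- make_pressure_field(cfg)
  pair <- render_interferogram(fld, cfg)
  map <- pressure_map(pair, cfg$eos)
  expect_equal(max(map$grid), max(fld$grid), tolerance = 0.05)
  expect_lt(max(abs(map$grid - fld$grid)) / max(fld$grid), 0.05)
  # identical images give a zero map
  pair0 <- interferogram_pair(pair$reference, pair$reference, 400, 2)
  map0 <- pressure_map(pair0, cfg$eos)
  expect_lt(max(abs(map0$grid)), 1e-9)
})

test_that("pressure_map localizes two separated pulses to the correct rows", {
  nr <- 256
  two <- gauss_bump(nr, nr, 0.5, 8, row0 = 90) +
    gauss_bump(nr, nr, 0.5, 8, row0 = 180)
  fld <- scalar_field(two, "pressure_MPa", 1)
  cfg <- sim_config(seed = 2)
  map <- pressure_map(render_interferogram(fld, cfg), cfg$eos)
  prof <- pressure_profile(map, axis = "rows")
  top <- prof$mean_MPa
  expect_lte(abs(which.max(top[1:128]) - 90), 1)
  expect_lte(abs(128 + which.max(top[129:nr]) - 180), 1)
})

test_that("pressure_profile reports per-position mean and spread", {
  const <- scalar_field(matrix(2, 32, 32), "pressure_MPa", 1.5)
  pr <- pressure_profile(const, axis = "rows")
  expect_equal(pr$mean_MPa, rep(2, 32))
  expect_equal(pr$sd_MPa, rep(0, 32))
  expect_equal(pr$position_um, (0:31) * 1.5)

  # translation-invariant ridge: sd ~ 0; iid noise raises sd toward sigma
  ridge <- matrix(gauss_bump(64, 1, 3, 7, row0 = 32)[, 1], 64, 64)
  pr2 <- pressure_profile(scalar_field(ridge, "pressure_MPa", 1), axis = "rows")
  expect_lt(max(pr2$sd_MPa), 1e-12)
  set.seed(9)
  noisy <- ridge + matrix(rnorm(64 * 64, 0, 0.2), 64, 64)
  pr3 <- pressure_profile(scalar_field(noisy, "pressure_MPa", 1), axis = "rows")
  expect_equal(mean(pr3$sd_MPa), 0.2, tolerance = 0.1)
  # Gaussian ridge profile keeps its amplitude
  expect_equal(max(pr2$mean_MPa), 3, tolerance = 1e-9)

  expect_error(pressure_profile(const, roi = c(0, 40, 1, 10)), "bounds error")
})

test_that("profile_fwhm matches closed forms and dense-grid sampling", {
  # Gaussian with sigma = 15.3 um -> FWHM = 2 sqrt(2 ln 2) sigma = 36.03 um
  x <- seq(0, 200, by = 2)
  g <- exp(-(x - 100)^2 / (2 * 15.3^2))
  pr <- structure(data.frame(position_um = x, mean_MPa = g, sd_MPa = 0),
                  class = c("pressure_profile", "data.frame"))
  expect_equal(profile_fwhm(pr), 2 * sqrt(2 * log(2)) * 15.3, tolerance = 0.5 / 36)
  # triangle of half-width w has FWHM w
  xt <- seq(0, 60, by = 1)
  tri <- pmax(0, 1 - abs(xt - 30) / 12)
  prt <- data.frame(position_um = xt, mean_MPa = tri)
  expect_equal(profile_fwhm(prt), 12, tolerance = 1e-9)
  # no crossing on one side
  mono <- data.frame(position_um = 0:20, mean_MPa = seq(0, 1, length.out = 21))
  expect_error(profile_fwhm(mono), "unbounded peak")
})

test_that("field TIFF IO round-trips values through the sidecar", {
  fld <- scalar_field(matrix(rnorm(256, 0, 3), 16, 16), "pressure_MPa", 2)
  path <- tempfile(fileext = ".tif")
  write_field_tiff(fld, path)
  back <- read_field_tiff(path)
  expect_equal(back$grid, fld$grid, tolerance = 1e-6)
  expect_equal(back$quantity, "pressure_MPa")
  expect_equal(back$pixel_size_um, 2)
})
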