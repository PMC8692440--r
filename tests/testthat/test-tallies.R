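test_that("specular reflection is exact and involutive", {
  st <- list(position = c(1, 2, 5), direction = c(0, 0, 1), energy = 123.456)
  face <- list(axis = 3, coord = 5)
  r <- reflect(st, face)
  expect_equal(r$direction, c(0, 0, -1))
  expect_identical(r$energy, st$energy)            # unchanged to the bit
  expect_equal(reflect(r, face)$direction, st$direction)
  # tangential components untouched
  st2 <- list(position = c(0, 0, 5), direction = c(0.6, 0.48, 0.64))
  r2 <- reflect(st2, face)
  expect_equal(r2$direction[1:2], st2$direction[1:2])
  expect_error(reflect(list(position = c(0, 0, 4), direction = c(0, 0, 1)),
                       face), "not on")
})

test_that("sphere-lattice mapping agrees with the brute-force nearest-centre oracle", {
  set.seed(11)
  R <- 360; nlat <- 179
  pts <- matrix(runif(3e4, 0, R * nlat), ncol = 3)
  idx <- sphere_index(pts, R, nlat)
  # oracle: nearest centre, inside iff within R/2
  ijk <- pmin(pmax(round(pts / R - 0.5), 0), nlat - 1)
  ctr <- (ijk + 0.5) * R
  inside <- rowSums((pts - ctr)^2) <= (R / 2)^2
  oracle <- ifelse(inside, ijk[, 1] + nlat * (ijk[, 2] + nlat * ijk[, 3]), NA)
  expect_equal(idx, oracle)
  # every point maps to at most one sphere; interstitial fraction ~ 1 - pi/6
  expect_equal(mean(is.na(idx)), 1 - pi / 6, tolerance = 0.02)
})

test_that("lineal-energy finalize: degenerate, hand-computed and chord cases", {
  d1 <- lineal_energy_finalize(rep(360, 50), R = 360)
  expect_equal(d1$y_F, 1.5)   # 360 eV over (2/3)*360 = 240 nm
  expect_equal(d1$y_D, 1.5)
  # two equally frequent events y = 1 and 3 -> y_F = 2, y_D = 2.5
  d2 <- lineal_energy_finalize(c(rep(1, 100), rep(3, 100)), already_y = TRUE)
  expect_equal(d2$y_F, 2)
  expect_equal(d2$y_D, 2.5)
  # mean chord divisor is exactly (2/3) * diameter
  eps <- 100
  d3 <- lineal_energy_finalize(eps, R = 300)
  expect_equal(d3$y_F, eps / (300 * 2 / 3))
  expect_error(lineal_energy_finalize(numeric(0), R = 300), "no lineal")
})

test_that("f(y) normalizes and y_D >= y_F on random spectra", {
  set.seed(8)
  for (k in 1:5) {
    y <- rlnorm(2000, meanlog = runif(1, -1, 2), sdlog = runif(1, 0.2, 1.5))
    fin <- lineal_energy_finalize(y, already_y = TRUE, ymax = 10)
    wid <- fin$fy$y_hi - fin$fy$y_lo
    expect_equal(sum(fin$fy$f * wid), 1, tolerance = 1e-9)
    expect_gte(fin$y_D, fin$y_F)    # Cauchy-Schwarz
    if (!is.na(fin$y_D_restricted)) expect_lte(fin$y_D_restricted, fin$y_D)
  }
})

test_that("radial dose finalize conserves energy and normalizes by shell mass", {
  edges <- c(0, 1, 2, 5, 10)
  E <- c(10, 20, 30, 40)
  prof <- radial_dose_finalize(E, edges, thickness_nm = 100, density = 1,
                               histories = 2)
  expect_equal(attr(prof, "total_energy"), sum(E))
  expect_equal(sum(prof$energy_eV), sum(E) / 2)
  # dose = E / mass; check one bin by hand
  mass_g <- pi * (2^2 - 1^2) * 100 * 1e-21 * 1
  expect_equal(prof$dose_Gy[2], (20 / 2) * 1.602176634e-19 / (mass_g * 1e-3))
  expect_true(all(diff(cumsum(prof$energy_eV)) >= 0))
})

test_that("thin-target spectrum tally integrates to the ionisation yield", {
  set.seed(2)
  births <- rexp(5000, 1 / 40)
  spec <- sdcs_spectrum_tally(births, n_protons = 100, n = 3.34e22,
                              thickness_cm = 1e-6)
  tot <- sum(spec$sdcs * (spec$E_hi - spec$E_lo)) * 3.34e22 * 1e-6
  expect_equal(tot, attr(spec, "ionisations_per_proton"), tolerance = 0.01)
})
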