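test_that("stopping-power anchors: TEG 30 MeV and water 1 MeV", {
  expect_equal(total_stopping_power(fix_teg, 30e6, "keV/um"), 1.9,
               tolerance = 0.05)
  # independent published proton tabulations give ~260.8 MeV cm^2/g at 1 MeV
  expect_equal(total_stopping_power(fix_water, 1e6, "MeV cm2/g"), 260.8,
               tolerance = 0.05)
  expect_equal(total_stopping_power(fix_water, 100e6, "MeV cm2/g"), 7.289,
               tolerance = 0.05)
})

test_that("above-peak ordering and unit consistency", {
  expect_lt(total_stopping_power(fix_water, 1e7),
            total_stopping_power(fix_water, 1e6))
  S <- total_stopping_power(fix_water, 1e6, "eV/cm")
  expect_equal(total_stopping_power(fix_water, 1e6, "eV/nm"), S * 1e-7)
  expect_equal(total_stopping_power(fix_water, 1e6, "MeV cm2/g"), S / 1e6)
})

test_that("linear density scaling and mixture self-consistency", {
  E <- c(1e5, 1e6, 3e7)
  expect_equal(total_stopping_power(material_water(2), E),
               2 * total_stopping_power(material_water(1), E))
  half <- load_material(list(name = "w+w", density = 1, constituents = list(
    list(species = "H2O", fraction = 0.5), list(species = "H2O", fraction = 0.5))))
  expect_equal(total_stopping_power(half, E),
               total_stopping_power(fix_water, E))
})

test_that("high-energy limit: E * S_tot grows logarithmically", {
  # log growth is the non-relativistic Bethe signature; test 10-100 MeV
  # (above 100 MeV the 1/beta^2 saturation makes E*S super-logarithmic)
  E <- exp(seq(log(1e7), log(1e8), length.out = 20))
  ES <- E * total_stopping_power(fix_water, E, "MeV cm2/g")
  expect_true(all(diff(ES) > 0))
  fit <- stats::lm(ES ~ log(E))
  expect_gt(summary(fit)$r.squared, 0.97)
  E2 <- exp(seq(log(1e8), log(1e9), length.out = 10))
  expect_true(all(diff(E2 * total_stopping_power(fix_water, E2,
                                                 "MeV cm2/g")) > 0))
})

test_that("piecewise construction is C1 at the knots", {
  for (Ek in c(0.02e6, 0.08e6, 0.5e6)) {
    h <- Ek * 1e-5
    dl <- (log(total_stopping_power(fix_water, Ek)) -
             log(total_stopping_power(fix_water, Ek - h))) / (h / Ek)
    dr <- (log(total_stopping_power(fix_water, Ek + h)) -
             log(total_stopping_power(fix_water, Ek))) / (h / Ek)
    expect_equal(dl, dr, tolerance = 1e-3)
  }
})

test_that("energies outside the supported range error", {
  expect_error(total_stopping_power(fix_water, 500), "range")
  expect_error(total_stopping_power(fix_water, 2e9), "range")
})

test_that("CSDA range is sane in water", {
  expect_equal(csda_range(fix_water, 1e6) * 1e4, 24, tolerance = 0.15)  # um
  expect_equal(csda_range(fix_water, 1e7), 0.12, tolerance = 0.15)      # cm
})
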