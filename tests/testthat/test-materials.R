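test_that("water material reproduces hand-derived densities", {
  w <- fix_water
  # n = rho * Na / M = 6.02214076e23 / 18.015
  expect_equal(w$number_density, 6.02214076e23 / sum(c(2 * 1.008, 15.999)),
               tolerance = 1e-3)
  expect_equal(w$number_density, 3.34e22, tolerance = 0.01)
  expect_equal(w$electron_density, 10 * w$number_density, tolerance = 1e-12)
  expect_equal(sum(w$shells$eff_occ), 10)
})

test_that("electron count is conserved per molecule/atom", {
  fe <- load_material(list(name = "iron", density = 7.874,
                           constituents = list(list(species = "Fe", fraction = 1))))
  expect_equal(sum(fe$shells$occ), 26)
  expect_equal(sum(fix_teg$shells$eff_occ),
               0.547 * (3 * 6 + 8 * 1) + 0.397 * 22 + 0.056 * 14,
               tolerance = 1e-12)
})

test_that("TEG uses molecular CO2 shells and elemental C, H, N shells", {
  sh <- fix_teg$shells
  expect_true(any(sh$species == "CO2" & sh$pset == "co2"))
  expect_true(any(grepl("^C:", sh$subshell)))    # propane decomposed
  expect_true(any(grepl("^N:", sh$subshell)))    # N2 decomposed
  expect_warning(load_material(list(name = "propane", density = 1,
                                    constituents = list(list(species = "C3H8",
                                                             fraction = 1)))),
                 "decomposing")
})

test_that("composition errors are caught", {
  expect_error(load_material(list(density = 1, constituents = list(
    list(species = "H2O", fraction = 0.6), list(species = "CO2", fraction = 0.5)
  ))), "sum to")
  expect_error(load_material(list(density = 1, constituents = list(
    list(species = "Xx2", fraction = 1)))), "Xx")
  expect_error(load_material(list(density = -1, constituents = list(
    list(species = "H2O", fraction = 1)))), "density")
})

test_that("densities scale linearly with mass density and molar fraction", {
  w1 <- material_water(1); w2 <- material_water(2)
  expect_equal(w2$number_density, 2 * w1$number_density)
  expect_equal(w2$electron_density, 2 * w1$electron_density)
})

test_that("mass-to-molar fraction conversion inverts", {
  x <- molar_from_mass_fractions(c("H2O", "CO2"), c(0.5, 0.5))
  expect_equal(sum(x), 1)
  # back to mass fractions
  mm <- c(18.015, 44.009)
  m <- x * mm / sum(x * mm)
  expect_equal(unname(m), c(0.5, 0.5), tolerance = 1e-3)
})

test_that("noble-gas analogy assigns Rudd parameter sets", {
  fe <- element_shells("Fe")
  outer <- as.list(fe[fe$subshell == "4s", ])
  expect_equal(assign_rudd_parameters(outer, "Fe"), "kr")
  for (ss in c("1s", "2p", "3d")) {
    expect_equal(assign_rudd_parameters(as.list(fe[fe$subshell == ss, ]), "Fe"),
                 "inner")
  }
  h2o <- protrax:::.species_shells("H2O")
  expect_equal(h2o$pset[h2o$subshell == "1b1"], "h2o")
  expect_equal(h2o$pset[h2o$subshell == "O1s"], "inner")
  # beyond the N shell there is no analogue
  expect_error(assign_rudd_parameters(list(n = 5), "Fe"), "explicit")
})

test_that("shell overrides and config round-trip work", {
  cfg <- list(name = "custom", density = 1,
              constituents = list(list(species = "H2O", fraction = 1)),
              shell_overrides = list(list(species = "H2O", subshell = "1b1",
                                          eps = 13.0)))
  m <- load_material(cfg)
  expect_equal(m$shells$eps[m$shells$subshell == "1b1"], 13.0)
  path <- tempfile(fileext = ".json")
  write_material_config(cfg, path)
  m2 <- read_material_config(path)
  expect_equal(m2$shells, m$shells)
  expect_equal(m2$number_density, m$number_density)
})
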