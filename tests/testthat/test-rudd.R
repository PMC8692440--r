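test_that("SDCS is finite and non-negative over wide scans", {
  Egrid <- 10^seq(-1, 5, length.out = 200)
  for (i in c(1, 5)) {
    sh <- as.list(fix_water$shells[i, ])
    for (Ep in c(1e4, 1e6, 3e7, 1e9)) {
      v <- rudd_sdcs(sh, Ep, Egrid)
      expect_true(all(is.finite(v)) && all(v >= 0))
    }
  }
  expect_error(rudd_sdcs(fake_shell(12), 1e6, -1), "E >= 0")
})

test_that("SDCS scales as the inverse cube of the potential at fixed scaled variables", {
  # the model prefactor S/eps is proportional to 1/eps^3: doubling eps while
  # holding the scaled speed (Ep/eps) and scaled energy (E/eps) fixed
  # reduces dsigma/dE by ~2^3 (the Ry/(4 eps) cutoff term perturbs slightly)
  w <- c(0.5, 2, 5)
  r <- rudd_sdcs(fake_shell(20), 1e6, w * 20) /
    rudd_sdcs(fake_shell(40), 2e6, w * 40)
  expect_equal(unname(r), rep(8, 3), tolerance = 0.10)
  # at fixed proton energy the integrated cross section also falls steeply
  # with eps (between the prefactor's cube and the F-factor compensation)
  expect_gt(total_shell_xs(fake_shell(20), 1e6) /
              total_shell_xs(fake_shell(40), 1e6), 2)
})

test_that("intermediate-region log-log slope of the SDCS approaches -3", {
  # pure (1+w)^-3 falloff modified upward by the hard-collision (F2 w) term
  sh <- fake_shell(12.61)
  Ep <- 30e6
  w <- 10^seq(0.3, 0.9, length.out = 40)
  y <- rudd_sdcs(sh, Ep, w * sh$eps)
  fit <- stats::lm(log(y) ~ log(1 + w))
  sl <- unname(coef(fit)[2])
  expect_lt(sl, -2.0)
  expect_gt(sl, -3.3)
})

test_that("adaptive quadrature agrees with the brute-force trapezoid oracle", {
  for (i in c(1, 4, 5)) {
    sh <- as.list(fix_water$shells[i, ])
    for (Ep in c(1e5, 1e6, 3e7)) {
      brute <- trapz_sdcs(sh, Ep)
      expect_equal(total_shell_xs(sh, Ep), brute, tolerance = 1e-4)
    }
  }
  # convergence: tightening the tolerance moves the result < 1e-5 relative
  sh <- as.list(fix_water$shells[1, ])
  a <- total_shell_xs(sh, 1e6, rel.tol = 1e-6)
  b <- total_shell_xs(sh, 1e6, rel.tol = 1e-9)
  expect_lt(abs(a - b) / b, 1e-5)
})

test_that("inner shells contribute far less than the outermost shell (Fe, 1 MeV)", {
  fe <- element_shells("Fe")
  outer <- as.list(cbind(fe[fe$subshell == "4s", ], pset = "kr"))
  inner <- as.list(cbind(fe[fe$subshell == "2p", ], pset = "inner"))
  outer$eps <- as.numeric(outer$eps); inner$eps <- as.numeric(inner$eps)
  expect_lt(total_shell_xs(inner, 1e6), 0.05 * total_shell_xs(outer, 1e6))
})

test_that("macroscopic cross section is linear in density and occupancy", {
  Sig1 <- macroscopic_ionisation_xs(material_water(1), 1e6)
  Sig2 <- macroscopic_ionisation_xs(material_water(2), 1e6)
  expect_equal(Sig2, 2 * Sig1, tolerance = 1e-9)
  expect_gt(Sig1, 0)
  # doubling all occupancies doubles Sigma (linearity in N_i)
  ov <- lapply(seq_len(5), function(i) {
    sh <- fix_water$shells[i, ]
    list(species = "H2O", subshell = sh$subshell, occ = 2 * sh$occ)
  })
  wd <- load_material(list(name = "w", density = 1,
                           constituents = list(list(species = "H2O", fraction = 1)),
                           shell_overrides = ov))
  expect_equal(macroscopic_ionisation_xs(wd, 1e6), 2 * Sig1, tolerance = 1e-6)
})

test_that("mean ionising loss rate: identity, oracle, and bound by S_tot at high energy", {
  r <- mean_ionising_loss_rate(fix_water, 1e6)
  expect_equal(r$total - r$kinetic, r$potential, tolerance = 1e-12)
  # brute-force double-quadrature oracle for the kinetic part
  kin_or <- fix_water$number_density *
    sum(vapply(seq_len(5), function(i) {
      trapz_sdcs(as.list(fix_water$shells[i, ]), 1e6, weight = function(E) E,
                 per_decade = 2048)
    }, 0))
  expect_equal(r$kinetic, kin_or, tolerance = 1e-3)
  # the potential part equals n * sum eps_i sigma_i exactly
  pot_or <- fix_water$number_density *
    sum(vapply(seq_len(5), function(i) {
      sh <- as.list(fix_water$shells[i, ])
      sh$eps * total_shell_xs(sh, 1e6)
    }, 0))
  expect_equal(r$potential, pot_or, tolerance = 1e-6)
  # at 30 MeV the ionising rate is a large fraction of, but below, S_tot
  r30 <- mean_ionising_loss_rate(fix_water, 30e6)
  S30 <- total_stopping_power(fix_water, 30e6)
  expect_gt(r30$total / S30, 0.5)
  expect_lt(r30$total / S30, 1.0)
})

test_that("secondary sampling matches shell weights and the quadrature CDF", {
  xs <- fix_xs_water
  Ep <- 1e6
  set.seed(42)
  n <- 1e5
  s <- sample_secondary(xs, Ep, n)
  expect_true(all(s$E >= 0) && all(is.finite(s$E)))

  # shell frequencies vs sigma_i proportions, 3 multinomial SE
  p <- vapply(seq_len(5), function(i) {
    total_shell_xs(as.list(fix_water$shells[i, ]), Ep)
  }, 0)
  p <- p / sum(p)
  obs <- tabulate(s$shell, 5) / n
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(obs - p) <= 3 * se + 1e-12))

  # KS against the quadrature-built mixture CDF at the 1% critical value
  Eg <- exp(seq(log(1e-3), log(1e5), by = log(10) / 256))
  f <- Reduce(`+`, lapply(seq_len(5), function(i) {
    rudd_sdcs(as.list(fix_water$shells[i, ]), Ep, Eg)
  }))
  cum <- c(0, cumsum(0.5 * (f[-1] + f[-length(f)]) * diff(Eg)))
  cum <- cum / cum[length(cum)]
  Fs <- stats::approx(Eg, cum, xout = pmin(pmax(s$E, min(Eg)), max(Eg)),
                      rule = 2)$y
  D <- max(abs(sort(Fs) - (seq_len(n) - 0.5) / n))
  expect_lt(D, 1.628 / sqrt(n))   # alpha = 0.01
})

test_that("below-threshold sampling errors out", {
  expect_error(sample_secondary(fix_xs_water, 1e9 * 1.01), "range")
})

test_that("cross-section CSV export writes the documented files", {
  dir <- tempfile()
  write_xs_csv(fix_xs_water, dir, Ep_sdcs = 1e6)
  expect_true(file.exists(file.path(dir, "sigma_Ep.csv")))
  expect_true(file.exists(file.path(dir, "sdcs_1e+06.csv")))
  sig <- utils::read.csv(file.path(dir, "sigma_Ep.csv"))
  expect_equal(nrow(sig), length(fix_xs_water$lEp))
})
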