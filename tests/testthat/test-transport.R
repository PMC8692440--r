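test_that("free-path sampling: closed forms and exponential mean", {
  xs <- fix_xs_water
  Sig <- xs_rates(xs, 1e6)$Sig_tot
  expect_equal(sample_free_path(xs, 1e6, r = exp(-1)), 1 / Sig)
  expect_lt(sample_free_path(xs, 1e6, r = 1 - 1e-12), 1e-11 / Sig)
  set.seed(1)
  n <- 1e5
  dL <- sample_free_path(xs, 1e6, n)
  se <- stats::sd(dL) / sqrt(n)
  expect_lt(abs(mean(dL) - 1 / Sig), 3 * se)
})

test_that("step energy update obeys the bookkeeping identity", {
  xs <- fix_xs_water
  for (Ep in c(2e5, 1e6, 3e7)) {
    r <- xs_rates(xs, Ep)
    for (dL in c(1e-8, 1 / r$Sig_tot, 10 / r$Sig_tot)) {
      u <- step_energy_update(Ep, xs, dL, shell = 1, Eprime = 50)
      # identity as documented: start - end = all deposits + electron - deficit
      expect_equal(Ep - u$E_D,
                   u$deposit_step + u$deposit_collision + u$electron_energy -
                     u$deficit,
                   tolerance = 1e-9 * Ep)
      expect_gte(u$deposit_step, 0)
      expect_gte(u$deposit_collision, 0)
      expect_lt(u$E_D, u$E_C)  # the collision always costs energy
    }
  }
  # unpayable collision terminates with local deposit
  u <- step_energy_update(1100, xs, 1e-9, shell = 5, Eprime = 1000)
  expect_true(u$terminated)
  expect_equal(u$E_D, 0)
})

test_that("emission kinematics closed forms and momentum audit", {
  mep <- 0.51099895e6 / 938.27208816e6
  Ep <- 1e6
  Emax <- 4 * mep * Ep
  k0 <- electron_emission_kinematics(Ep, Emax, 12.6, phi = 0)
  expect_equal(k0$theta, 0, tolerance = 1e-9)
  expect_true(k0$clamped)
  k60 <- electron_emission_kinematics(Ep, Emax / 4, 12.6, phi = 1)
  expect_equal(k60$theta, pi / 3, tolerance = 1e-12)
  expect_equal(sum(k60$dir_electron * c(0, 0, 1)), cos(pi / 3),
               tolerance = 1e-12)

  # momentum audit: initial = electron + proton + residual, exactly
  for (Eprime in c(1, 100, 2000)) {
    k <- electron_emission_kinematics(Ep, Eprime, 12.6, phi = 2.2)
    p_i <- sqrt(2 * 938.27208816e6 * Ep) * c(0, 0, 1)
    p_e <- sqrt(2 * 0.51099895e6 * Eprime) * k$dir_electron
    p_p <- sqrt(2 * 938.27208816e6 * (Ep - Eprime - 12.6)) * k$dir_proton
    expect_equal(p_i, p_e + p_p + k$residual_momentum,
                 tolerance = 1e-9 * sqrt(sum(p_i^2)))
  }

  # typical residual magnitude is small but non-zero (order 0.01-0.1 MeV/c)
  k <- electron_emission_kinematics(Ep, 500, 12.6, phi = 0.4)
  rm <- sqrt(sum(k$residual_momentum^2))
  expect_gt(rm, 1e2)
  expect_lt(rm, 1e6)
})

test_that("closed-geometry transport conserves energy and decreases proton energy", {
  m <- transport_proton(fix_water, 2e5, list(type = "box", side_nm = 2e6),
                        histories = 10, seed = 3, electrons = TRUE,
                        cut = list(threshold = 1e3), xs = fix_xs_water,
                        record_events = TRUE)
  expect_lt(max(abs(m$balance)), 1e-6)
  mono <- tapply(m$Ep_seq, m$Ep_seq_hist, function(v) all(diff(v) < 0))
  expect_true(all(mono))
  # event record covers deposits and closes the budget too
  ev <- m$events
  expect_true(all(ev$E > 0))
  expect_setequal(unique(ev$mech), c(0, 1, 2, 3, 4))
})

test_that("projected range reproduces the CSDA integral oracle", {
  for (E in c(1e6, 1e7)) {
    cfg <- benchmark_config("range", E / 1e6, "water", histories = 40, seed = 9)
    res <- run_benchmark(cfg, xs = fix_xs_water)
    expect_equal(res$summary$mean_range_cm, csda_range(fix_water, E),
                 tolerance = 0.05)
  }
})

test_that("identical (config, seed) runs are byte-identical; histories are order-independent", {
  cfg <- benchmark_config("lineal", 30, "teg", histories = 8, seed = 77,
                          R_nm = 360)
  a <- run_benchmark(cfg, xs = fix_xs_teg)
  b <- run_benchmark(cfg, xs = fix_xs_teg)
  expect_identical(jsonlite::toJSON(a$summary, auto_unbox = TRUE, digits = NA),
                   jsonlite::toJSON(b$summary, auto_unbox = TRUE, digits = NA))
  # per-history streams: running fewer histories reproduces a prefix
  m1 <- transport_proton(fix_teg, 30e6,
                         list(type = "sphere_lattice", R_nm = 360, nlat = 179,
                              angle_max_deg = 30),
                         histories = 3, seed = 5, cut = list(frac = 0.005),
                         xs = fix_xs_teg)
  m2 <- transport_proton(fix_teg, 30e6,
                         list(type = "sphere_lattice", R_nm = 360, nlat = 179,
                              angle_max_deg = 30),
                         histories = 5, seed = 5, cut = list(frac = 0.005),
                         xs = fix_xs_teg)
  expect_equal(m1$dep_total_hist, m2$dep_total_hist[1:3])
})
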