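test_that("config validation names the offending fields", {
  expect_error(benchmark_config("lineal", -3), "energy_MeV")
  cfg <- benchmark_config("lineal", 30, histories = 5)
  cfg$R_nm <- -1
  expect_error(validate_config(cfg), "R_nm")
  cfg$histories <- 0
  expect_error(validate_config(cfg), "histories.*R_nm|R_nm.*histories")
  expect_error(benchmark_config("nope", 30), "arg")
})

test_that("run-config JSON round-trip is idempotent", {
  cfg <- benchmark_config("lineal", 30, "teg", histories = 12, seed = 3)
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  write_run_config(cfg, p1)
  cfg2 <- read_run_config(p1)
  write_run_config(cfg2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(cfg2$R_nm, cfg$R_nm)
})

test_that("projected range grows with beam energy", {
  r1 <- run_benchmark(benchmark_config("range", 1, histories = 10, seed = 2),
                      xs = fix_xs_water)
  r2 <- run_benchmark(benchmark_config("range", 5, histories = 10, seed = 2),
                      xs = fix_xs_water)
  expect_lt(r1$summary$mean_range_cm, r2$summary$mean_range_cm)
})

test_that("thin-target run reproduces the analytic SDCS prediction", {
  cfg <- benchmark_config("sdcs", 1, "water", histories = 3000, seed = 6)
  mat <- protrax:::.config_material(cfg)
  xs <- build_xs_table(mat)
  res <- run_benchmark(cfg, xs = xs)
  spec <- res$spectrum
  # analytic per-molecule SDCS summed over shells at the beam energy
  pred <- Reduce(`+`, lapply(seq_len(nrow(mat$shells)), function(i) {
    mat$shells$weight[i] *
      rudd_sdcs(as.list(mat$shells[i, ]), 1e6, spec$E_mid)
  }))
  sel <- which(spec$sdcs > 0 & pred > 0)
  cnt <- spec$sdcs[sel] * (spec$E_hi - spec$E_lo)[sel] * cfg$histories *
    mat$number_density * cfg$thickness_nm * 1e-7
  keep <- cnt >= 40                      # bins with decent statistics
  ratio <- spec$sdcs[sel][keep] / pred[sel][keep]
  relse <- 1 / sqrt(cnt[keep])
  expect_true(all(abs(ratio - 1) < 4 * relse + 0.05))
  # the spectrum falls steeply with energy
  expect_gt(spec$sdcs[sel][1] / spec$sdcs[sel][length(sel)], 100)
  # integral = ionisations per proton
  expect_equal(sum(spec$sdcs * (spec$E_hi - spec$E_lo)) *
                 mat$number_density * cfg$thickness_nm * 1e-7,
               res$summary$ionisations_per_proton, tolerance = 0.02)
})

test_that("benchmark outputs are written to disk", {
  out <- tempfile()
  cfg <- benchmark_config("lineal", 30, "teg", histories = 5, seed = 1)
  res <- run_benchmark(cfg, out = out, xs = fix_xs_teg)
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_true(file.exists(file.path(out, "fy.csv")))
  s <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(s$y_D, res$summary$y_D)
  expect_match(s$config_hash, "^[0-9a-f]+$")
})

test_that("CLI argument parsing and subcommands work", {
  opts <- protrax:::.cli_parse(c("--material", "water", "--out", "x.csv"))
  expect_equal(opts$material, "water")
  path <- tempfile(fileext = ".csv")
  protrax_cli(c("stopping", "--material", "teg", "--out", path))
  df <- utils::read.csv(path)
  expect_true(all(df$S_eV_per_nm > 0))
  expect_error(protrax_cli(c("bogus")), "subcommand")
})
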