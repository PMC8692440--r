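# Shared fixtures: materials and cross-section tables are moderately
# expensive (fractions of a second) and deterministic, so build them once.

fix_water <- material_water()
fix_teg <- suppressWarnings(material_teg())
fix_xs_water <- build_xs_table(fix_water)
fix_xs_teg <- build_xs_table(fix_teg)

# artificial single-shell "material" for arithmetic checks
fake_shell <- function(eps, occ = 2, pset = "h2o") {
  list(eps = eps, occ = occ, pset = pset)
}

# fine-grid trapezoid oracle for integrals of weight(E) * sdcs(E)
trapz_sdcs <- function(shell, Ep, weight = function(E) 1,
                       lo = 1e-4, hi = NULL, per_decade = 512) {
  if (is.null(hi)) hi <- protrax:::.rudd_Emax(shell, Ep)
  E <- exp(seq(log(lo), log(hi), by = log(10) / per_decade))
  f <- weight(E) * rudd_sdcs(shell, Ep, E)
  sum(0.5 * (f[-1] + f[-length(f)]) * diff(E))
}
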