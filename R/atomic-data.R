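# Bundled atomic data: subshell binding energies / occupancies, atomic
# weights, and mean excitation energies (I-values) for the stopping model.
#
# The subshell table is a curated transcription of standard atomic binding
# energies (outermost subshell = first ionisation potential; inner subshells
# = photoelectron binding energies).  It covers the elements needed by the
# bundled materials (tissue-equivalent gas, water, common detector media) and
# the worked examples; extending it is data entry, not code.

.atomic_weights <- c(
  H = 1.008, He = 4.0026, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Ne = 20.180, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.948,
  Fe = 55.845, Kr = 83.798
)

.atomic_numbers <- c(
  H = 1, He = 2, C = 6, N = 7, O = 8, F = 9, Ne = 10, Si = 14, P = 15,
  S = 16, Cl = 17, Ar = 18, Fe = 26, Kr = 36
)

# ICRU-style elemental mean excitation energies, eV
.ivalues <- c(
  H = 19.2, He = 41.8, C = 78.0, N = 82.0, O = 95.0, F = 115.0, Ne = 137.0,
  Si = 173.0, P = 173.0, S = 180.0, Cl = 174.0, Ar = 188.0, Fe = 286.0,
  Kr = 352.0
)

# subshell: spectroscopic label; n: principal quantum number; eps: binding
# energy (eV); occ: electrons in the subshell for the ground-state atom.
.element_shells_raw <- list(
  H  = list(c("1s", 1, 13.598, 1)),
  He = list(c("1s", 1, 24.587, 2)),
  C  = list(c("1s", 1, 288.0, 2), c("2s", 2, 16.59, 2), c("2p", 2, 11.260, 2)),
  N  = list(c("1s", 1, 403.0, 2), c("2s", 2, 20.33, 2), c("2p", 2, 14.534, 3)),
  O  = list(c("1s", 1, 538.0, 2), c("2s", 2, 28.48, 2), c("2p", 2, 13.618, 4)),
  F  = list(c("1s", 1, 694.0, 2), c("2s", 2, 37.85, 2), c("2p", 2, 17.423, 5)),
  Ne = list(c("1s", 1, 870.2, 2), c("2s", 2, 48.47, 2), c("2p", 2, 21.565, 6)),
  Si = list(c("1s", 1, 1839.0, 2), c("2s", 2, 149.7, 2), c("2p", 2, 99.8, 6),
            c("3s", 3, 13.46, 2), c("3p", 3, 8.152, 2)),
  P  = list(c("1s", 1, 2145.5, 2), c("2s", 2, 189.0, 2), c("2p", 2, 136.0, 6),
            c("3s", 3, 16.15, 2), c("3p", 3, 10.487, 3)),
  S  = list(c("1s", 1, 2472.0, 2), c("2s", 2, 230.9, 2), c("2p", 2, 163.6, 6),
            c("3s", 3, 20.20, 2), c("3p", 3, 10.360, 4)),
  Cl = list(c("1s", 1, 2822.4, 2), c("2s", 2, 270.0, 2), c("2p", 2, 202.0, 6),
            c("3s", 3, 25.30, 2), c("3p", 3, 12.968, 5)),
  Ar = list(c("1s", 1, 3205.9, 2), c("2s", 2, 326.3, 2), c("2p", 2, 249.2, 6),
            c("3s", 3, 29.24, 2), c("3p", 3, 15.760, 6)),
  Fe = list(c("1s", 1, 7112.0, 2), c("2s", 2, 844.6, 2), c("2p", 2, 715.0, 6),
            c("3s", 3, 91.3, 2), c("3p", 3, 52.7, 6), c("3d", 3, 8.9, 6),
            c("4s", 4, 7.902, 2)),
  Kr = list(c("1s", 1, 14326.0, 2), c("2s", 2, 1921.0, 2), c("2p", 2, 1678.0, 6),
            c("3s", 3, 292.8, 2), c("3p", 3, 214.4, 6), c("3d", 3, 95.0, 10),
            c("4s", 4, 27.51, 2), c("4p", 4, 14.000, 6))
)

.element_shells <- do.call(rbind, lapply(names(.element_shells_raw), function(sym) {
  rows <- .element_shells_raw[[sym]]
  data.frame(
    element  = sym,
    subshell = vapply(rows, `[`, "", 1),
    n        = as.integer(vapply(rows, `[`, "", 2)),
    eps      = as.numeric(vapply(rows, `[`, "", 3)),
    occ      = as.numeric(vapply(rows, `[`, "", 4)),
    stringsAsFactors = FALSE
  )
}))

#' Electron shells of an element
#'
#' Subshell binding energies and occupancies from the bundled atomic table.
#'
#' @param element Element symbol, e.g. `"C"`.
#' @return A data frame with columns `element`, `subshell`, `n`, `eps` (eV),
#'   `occ`.
#' @export
element_shells <- function(element) {
  out <- .element_shells[.element_shells$element == element, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("element '", element, "' is not in the bundled shell table", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

# Molecular registry: species with a known molecular orbital structure.
# `core = TRUE` marks atomic-core shells (assigned the inner-shell Rudd set);
# valence shells use the species' native parameter set.  `I_eV` is a
# compound mean excitation energy override for the stopping model.
.molecule_registry <- list(
  H2O = list(
    pset = "h2o", I_eV = 75.0,
    shells = data.frame(
      subshell = c("1b1", "3a1", "1b2", "2a1", "O1s"),
      eps = c(12.61, 14.73, 18.55, 32.2, 539.7),
      occ = c(2, 2, 2, 2, 2),
      core = c(FALSE, FALSE, FALSE, FALSE, TRUE)
    )
  ),
  CO2 = list(
    pset = "co2", I_eV = NA_real_,
    shells = data.frame(
      subshell = c("1pig", "1piu", "3sgu", "4sgg", "2sgu", "3sgg", "C1s", "O1s"),
      eps = c(13.78, 17.59, 18.08, 19.40, 37.6, 41.5, 297.7, 541.3),
      occ = c(4, 4, 2, 2, 2, 2, 2, 4),
      core = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
    )
  ),
  CH4 = list(
    pset = "ch4", I_eV = NA_real_,
    shells = data.frame(
      subshell = c("1t2", "2a1", "C1s"),
      eps = c(12.61, 22.9, 290.7),
      occ = c(6, 2, 2),
      core = c(FALSE, FALSE, TRUE)
    )
  ),
  H2 = list(
    pset = "h2", I_eV = NA_real_,
    shells = data.frame(subshell = "1sg", eps = 15.43, occ = 2, core = FALSE)
  ),
  O2 = list(
    pset = "o2", I_eV = NA_real_,
    shells = data.frame(
      subshell = c("1pig", "1piu", "3sgg", "2sgu", "2sgg", "O1s"),
      eps = c(12.07, 16.10, 18.17, 25.0, 40.0, 543.1),
      occ = c(2, 4, 2, 2, 2, 4),
      core = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
    )
  )
)

# noble-gas analogue for the outermost shell, keyed by principal quantum number
.noble_by_n <- c("he", "ne", "ar", "kr")

# elements whose native Rudd set exists (the noble gases themselves)
.native_element_pset <- c(He = "he", Ne = "ne", Ar = "ar", Kr = "kr")
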