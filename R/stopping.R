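# Total proton stopping power: Bethe formula above 0.5 MeV, a
# velocity-proportional (Lindhard-Scharff-like) branch below the ~0.08 MeV
# maximum, and C1 log-log cubic Hermite bridges in between.  Mixtures follow
# Bragg additivity over the material's stopping components (elements, plus
# compound I-value overrides such as water at 75 eV).

.bethe_mass_stopping <- function(E_MeV, zoa, I_eV) {
  # MeV cm^2 / g;  log argument regularised with +1 so the expression stays
  # positive at low energy (negligible above ~1 MeV, the bridge owns lower E)
  g <- 1 + E_MeV / .const$mpc2_MeV
  b2 <- 1 - 1 / g^2
  x <- 2 * .const$mec2_MeV * 1e6 * b2 * g^2 / I_eV
  .const$K_bethe * zoa / b2 * (log1p(x) - b2)
}

# knots of the low-energy construction (MeV)
.stop_E_vlow <- 0.02
.stop_E_peak <- 0.08
.stop_E_high <- 0.5
.stop_power_low <- 0.45        # S ~ E^0.45 below the low knot (velocity-like)
.stop_S_peak_water <- 820      # MeV cm^2/g at the water stopping maximum
.stop_zoa_water <- 10 / 18.015

.hermite_loglog <- function(E, E0, S0, m0, E1, S1, m1) {
  h <- log(E1 / E0)
  t <- (log(E) - log(E0)) / h
  t2 <- t * t; t3 <- t2 * t
  lS <- (2 * t3 - 3 * t2 + 1) * log(S0) + (t3 - 2 * t2 + t) * h * m0 +
    (-2 * t3 + 3 * t2) * log(S1) + (t3 - t2) * h * m1
  exp(lS)
}

# mass stopping power of one component, MeV cm^2/g, vectorised in E_MeV
.component_mass_stopping <- function(E_MeV, zoa, I_eV) {
  S_pk <- .stop_S_peak_water * zoa / .stop_zoa_water
  S_vlow <- S_pk * (.stop_E_vlow / .stop_E_peak)^.stop_power_low
  # Bethe value and log-log slope at the high knot
  eh <- .stop_E_high
  Sh <- .bethe_mass_stopping(eh, zoa, I_eV)
  dh <- 1e-4
  mh <- log(.bethe_mass_stopping(eh * (1 + dh), zoa, I_eV) / Sh) / log1p(dh)

  out <- numeric(length(E_MeV))
  lo <- E_MeV <= .stop_E_vlow
  mid1 <- E_MeV > .stop_E_vlow & E_MeV <= .stop_E_peak
  mid2 <- E_MeV > .stop_E_peak & E_MeV <= .stop_E_high
  hi <- E_MeV > .stop_E_high
  out[lo] <- S_vlow * (E_MeV[lo] / .stop_E_vlow)^.stop_power_low
  out[mid1] <- .hermite_loglog(E_MeV[mid1], .stop_E_vlow, S_vlow,
                               .stop_power_low, .stop_E_peak, S_pk, 0)
  out[mid2] <- .hermite_loglog(E_MeV[mid2], .stop_E_peak, S_pk, 0, eh, Sh, mh)
  out[hi] <- .bethe_mass_stopping(E_MeV[hi], zoa, I_eV)
  out
}

#' Total stopping power of protons in a material
#'
#' Bragg-additive over the material's stopping components.  Supported proton
#' energies: 1 keV to 1 GeV.
#'
#' @param material A `protrax_material`.
#' @param E Proton kinetic energy (eV, vectorised).
#' @param units One of `"eV/cm"`, `"eV/nm"`, `"keV/um"`, `"MeV cm2/g"`.
#' @return Stopping power in the requested units.
#' @examples
#' total_stopping_power(material_teg(), 30e6, units = "keV/um")  # ~1.9
#' @export
total_stopping_power <- function(material, E,
                                 units = c("eV/cm", "eV/nm", "keV/um", "MeV cm2/g")) {
  units <- match.arg(units)
  if (any(E < 1e3 - 1e-9) || any(E > 1e9 + 1e-9)) {
    stop("proton energy outside the supported range [1 keV, 1 GeV]",
         call. = FALSE)
  }
  E_MeV <- E / 1e6
  comp <- material$stopping
  S_mass <- 0
  for (i in seq_len(nrow(comp))) {
    S_mass <- S_mass + comp$mass_fraction[i] *
      .component_mass_stopping(E_MeV, comp$zoa[i], comp$I_eV[i])
  }
  S_cm <- S_mass * material$mass_density * 1e6   # eV/cm
  switch(units,
         "eV/cm" = S_cm,
         "eV/nm" = S_cm * 1e-7,
         "keV/um" = S_cm * 1e-7,   # numerically identical to eV/nm
         "MeV cm2/g" = S_mass)
}

#' CSDA range by quadrature of the reciprocal stopping power
#'
#' \eqn{R = \int_{E_{cut}}^{E_0} dE / S_{tot}(E)}; used as the independent
#' oracle for the projected-range benchmark.
#'
#' @param material A `protrax_material`.
#' @param E0 Initial proton energy (eV).
#' @param E_cut Lower integration limit (eV), default 1 keV (table floor).
#' @return Range in cm.
#' @export
csda_range <- function(material, E0, E_cut = 1e3) {
  stats::integrate(function(E) 1 / total_stopping_power(material, E),
                   E_cut, E0, rel.tol = 1e-8, subdivisions = 800L)$value
}

#' Dump a stopping-power curve as CSV
#'
#' @param material A `protrax_material`.
#' @param path Output CSV path.
#' @param E Energy grid (eV).
#' @export
write_stopping_csv <- function(material, path,
                               E = exp(seq(log(1e3), log(1e9), length.out = 481))) {
  df <- data.frame(E_eV = E,
                   S_eV_per_nm = total_stopping_power(material, E, "eV/nm"),
                   S_MeV_cm2_g = total_stopping_power(material, E, "MeV cm2/g"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
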