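# Geometries and scorers: reflective regions, sphere-lattice lineal-energy
# tally, radial dose profile, secondary-electron spectrum, projected range.

#' Specular reflection at a boundary face
#'
#' @param state List with `position` and `direction` (unit 3-vector).
#' @param face List with `axis` (1-3) and `coord`; the state must lie on the
#'   face and be outgoing.
#' @return The reflected state: normal direction component negated, energy
#'   and tangential components untouched.
#' @export
reflect <- function(state, face) {
  ax <- face$axis
  if (abs(state$position[ax] - face$coord) > 1e-9) {
    stop("state is not on the reflective face", call. = FALSE)
  }
  state$direction[ax] <- -state$direction[ax]
  state
}

#' Map points to sphere-lattice sites
#'
#' Simple-cubic lattice of touching spheres of diameter `R` filling the cube
#' `[0, nlat*R]^3`.  A point belongs to the sphere of its cell iff it lies
#' within `R/2` of the cell centre; interstitial points map to `NA`.
#'
#' @param points Matrix (n x 3) of coordinates (nm).
#' @param R Sphere diameter (nm).
#' @param nlat Spheres per cube edge (default 179).
#' @return Integer site index (0-based, `ix + nlat*(iy + nlat*iz)`) or `NA`.
#' @export
sphere_index <- function(points, R, nlat = 179L) {
  points <- matrix(points, ncol = 3)
  ijk <- pmin(pmax(floor(points / R), 0), nlat - 1)
  ctr <- (ijk + 0.5) * R
  inside <- rowSums((points - ctr)^2) <= (R / 2)^2
  idx <- ijk[, 1] + nlat * (ijk[, 2] + nlat * ijk[, 3])
  ifelse(inside, idx, NA)
}

#' Finalize a lineal-energy tally
#'
#' Converts per-(history, sphere) energy deposits into lineal energies
#' \eqn{y = \varepsilon / \bar{\ell}} with mean chord \eqn{\bar{\ell} = (2/3) R}
#' for a sphere of diameter R, and computes the single-event distribution
#' f(y), its frequency mean \eqn{y_F} and dose mean
#' \eqn{y_D = \int y^2 f dy / \int y f dy}.  Moments are computed from the
#' raw event list; the histogram is for plotting/export.
#'
#' @param eps Per-(history, sphere) deposited energies (eV), or directly
#'   lineal energies if `already_y = TRUE`.
#' @param R Sphere diameter (nm).
#' @param ymax Optional upper cut for a restricted \eqn{y_D} (keV/um).
#' @param bins_per_decade Histogram resolution.
#' @param already_y Set when `eps` already holds y values (keV/um).
#' @return List with `y_F`, `y_D`, `y_D_restricted` (if `ymax` given),
#'   `n_events`, and a data frame `fy` (bin edges, f(y), y*f(y), cumulative).
#' @export
lineal_energy_finalize <- function(eps, R = NULL, ymax = NULL,
                                   bins_per_decade = 20, already_y = FALSE) {
  if (length(eps) == 0) stop("no lineal-energy events to finalize", call. = FALSE)
  y <- if (already_y) eps else eps / (R * 2 / 3)  # eV/nm == keV/um
  y <- y[y > 0]
  y_F <- mean(y)
  y_D <- sum(y^2) / sum(y)
  out <- list(y_F = y_F, y_D = y_D, n_events = length(y))
  if (!is.null(ymax)) {
    yr <- y[y <= ymax]
    out$y_D_restricted <- if (length(yr)) sum(yr^2) / sum(yr) else NA_real_
  }
  lo <- floor(log10(min(y))); hi <- ceiling(log10(max(y)))
  if (hi <= lo) hi <- lo + 1          # degenerate single-value spectra
  edges <- 10^seq(lo, hi, by = 1 / bins_per_decade)
  cnt <- graphics::hist(y, breaks = edges, plot = FALSE)$counts
  wid <- diff(edges)
  f <- cnt / (sum(cnt) * wid)
  ymid <- sqrt(edges[-1] * edges[-length(edges)])
  out$fy <- data.frame(y_lo = edges[-length(edges)], y_hi = edges[-1],
                       f = f, yf = ymid * f,
                       cumulative = cumsum(cnt) / sum(cnt))
  stopifnot(abs(sum(out$fy$f * wid) - 1) < 1e-9)
  out
}

#' Finalize a radial dose tally
#'
#' @param energy_eV Energy per radial bin (eV), summed over histories.
#' @param edges Radial bin edges (nm), ascending, length `length(energy_eV)+1`.
#' @param thickness_nm Cylinder thickness (nm).
#' @param density Mass density (g/cm^3).
#' @param histories Number of primaries.
#' @return Data frame with bin edges, energy per history, and dose (Gy) per
#'   history; plus attribute `total_energy` (eV).
#' @export
radial_dose_finalize <- function(energy_eV, edges, thickness_nm, density,
                                 histories) {
  stopifnot(length(edges) == length(energy_eV) + 1)
  r1 <- edges[-length(edges)]; r2 <- edges[-1]
  vol_cm3 <- pi * (r2^2 - r1^2) * thickness_nm * 1e-21
  mass_g <- vol_cm3 * density
  eV_per_hist <- energy_eV / histories
  dose_Gy <- eV_per_hist * 1.602176634e-19 / (mass_g * 1e-3)
  out <- data.frame(r_lo = r1, r_hi = r2, energy_eV = eV_per_hist,
                    dose_Gy = dose_Gy)
  attr(out, "total_energy") <- sum(energy_eV)
  out
}

#' Secondary-electron production spectrum from birth energies
#'
#' Thin-target estimator of the singly-differential cross section:
#' counts per primary per unit ejected-electron energy divided by the areal
#' density `n * t`.
#'
#' @param births Ejected-electron energies at birth (eV).
#' @param n_protons Number of primaries.
#' @param n Scatterer number density (formula units per cm^3).
#' @param thickness_cm Target thickness (cm).
#' @param bins_per_decade Histogram resolution.
#' @return Data frame with `E_lo`, `E_hi`, `E_mid` (eV) and `sdcs`
#'   (cm^2/eV per formula unit); attribute `ionisations_per_proton`.
#' @export
sdcs_spectrum_tally <- function(births, n_protons, n, thickness_cm,
                                bins_per_decade = 16) {
  stopifnot(n_protons >= 1)
  lo <- floor(log10(max(min(births), 1e-2)))
  hi <- ceiling(log10(max(births)))
  edges <- 10^seq(lo, hi, by = 1 / bins_per_decade)
  b <- births[births >= edges[1] & births <= edges[length(edges)]]
  cnt <- graphics::hist(b, breaks = edges, plot = FALSE)$counts
  wid <- diff(edges)
  out <- data.frame(E_lo = edges[-length(edges)], E_hi = edges[-1],
                    E_mid = sqrt(edges[-1] * edges[-length(edges)]),
                    sdcs = cnt / (n_protons * wid * n * thickness_cm))
  attr(out, "ionisations_per_proton") <- length(births) / n_protons
  out
}

# log-spaced radial bin edges with a leading zero bin so on-axis deposits
# are scored
radial_edges_default <- function(rmin = 0.1, rmax = 1e9, per_decade = 16) {
  c(0, 10^seq(log10(rmin), log10(rmax), by = 1 / per_decade))
}
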