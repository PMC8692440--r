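# Free-flight sampling, restricted stopping-power step bookkeeping, and
# binary-collision emission kinematics.  These are the reference (R)
# implementations of the per-step physics; the compiled transport engine
# inlines the same arithmetic.

#' Sample ionisation-limited free flight lengths
#'
#' \eqn{dL = -\ln(r) / \Sigma_{ion}(E_p)} with r uniform on (0,1).
#'
#' @param xs A `protrax_xs` table.
#' @param Ep Proton kinetic energy (eV, scalar).
#' @param n Number of samples.
#' @param r Optional uniform deviates (for closed-form checks); defaults to
#'   R's RNG.
#' @return Flight lengths in cm.
#' @export
sample_free_path <- function(xs, Ep, n = 1, r = NULL) {
  Sig <- .interp_Ep(xs, xs$Sig_tot, Ep)
  if (Sig <= 0) stop("Sigma_ion is zero at Ep = ", Ep, call. = FALSE)
  if (is.null(r)) r <- stats::runif(n)
  -log(r) / Sig
}

#' One restricted-stopping-power energy update
#'
#' Applies the energy-budget bookkeeping across one free flight ending in an
#' ionisation: the continuous (non-ionising) loss is the total stopping
#' power minus the mean ionising rate, floored at zero; the collision then
#' costs the sampled shell's ionisation potential plus the ejected-electron
#' energy.
#'
#' @param Ep_start Proton energy at the start of the flight (eV).
#' @param xs A `protrax_xs` table.
#' @param dL Flight length (cm).
#' @param shell Shell index (into `xs$material$shells`) of the sampled
#'   ionisation.
#' @param Eprime Sampled ejected-electron energy (eV).
#' The bookkeeping energy may locally *rise* along the flight (pre-collision
#' energy above the flight-start energy) when the mean ionising rate exceeds
#' the total stopping power -- an acknowledged artefact of combining two
#' independent fits.  Tally deposits are never negative: the continuous
#' deposit is floored at zero and the floored-away amount is repaid by
#' reducing the collision-point (ionisation-potential) deposit, which keeps
#' the per-step energy identity exact.
#'
#' @return List with `E_C` (pre-collision energy, Eq.-7-style bookkeeping),
#'   `E_D` (post-collision), `deposit_step` (continuous deposit along the
#'   flight, >= 0), `deposit_collision` (>= 0), `electron_energy`, `deficit`
#'   (unrepaid floored amount, almost always 0), `floored` and `terminated`
#'   (TRUE when the collision could not be paid for and the history ends
#'   with the remaining energy deposited locally).  Identity:
#'   `Ep_start - E_D = deposit_step + deposit_collision + electron_energy -
#'   deficit`.
#' @export
step_energy_update <- function(Ep_start, xs, dL, shell, Eprime) {
  stopifnot(Ep_start > 0, dL >= 0)
  r <- xs_rates(xs, Ep_start)
  rate_book <- r$Stot - r$Lkin - r$Lpot
  floored <- rate_book < 0
  dep_step <- max(rate_book, 0) * dL
  deficit <- max(-rate_book, 0) * dL
  E_C <- Ep_start - rate_book * dL
  eps_I <- xs$eps[shell]
  if (E_C <= Eprime + eps_I) {
    return(list(E_C = E_C, E_D = 0, deposit_step = dep_step,
                deposit_collision = max(E_C - deficit, 0),
                electron_energy = 0, deficit = max(deficit - E_C, 0),
                floored = floored, terminated = TRUE))
  }
  dep_coll <- eps_I - deficit
  list(E_C = E_C, E_D = E_C - Eprime - eps_I, deposit_step = dep_step,
       deposit_collision = max(dep_coll, 0), electron_energy = Eprime,
       deficit = max(-dep_coll, 0), floored = floored, terminated = FALSE)
}

# rotate unit vector `axis` by polar angle (cos ct) and azimuth phi
.rotate_direction <- function(axis, ct, phi) {
  st <- sqrt(max(0, 1 - ct * ct))
  # orthonormal frame around axis
  if (abs(axis[3]) < 0.99) u <- c(0, 0, 1) else u <- c(1, 0, 0)
  e1 <- u - sum(u * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  ct * axis + st * (cos(phi) * e1 + sin(phi) * e2)
}

#' Secondary-electron emission kinematics
#'
#' Non-relativistic binary collision with a free electron: the polar angle
#' of the ejected electron relative to the proton satisfies
#' \eqn{\cos^2\theta = E' / E'_{max}} with \eqn{E'_{max} = 4 (m_e/m_p) E_p};
#' the azimuth is uniform.  The proton direction is updated from vector
#' momentum balance, and the momentum that the bookkeeping energy
#' (`Ep_after`) cannot carry is assigned to the target atom as a residual.
#' If the sampled energy implies \eqn{|\cos\theta| > 1} the electron is
#' emitted exactly forward (clamped).
#'
#' @param Ep Proton kinetic energy before the collision (eV).
#' @param Eprime Ejected-electron kinetic energy (eV).
#' @param eps_I Ionisation potential of the sampled shell (eV).
#' @param dir_p Proton direction (unit 3-vector).
#' @param Ep_after Proton energy after the collision from the bookkeeping
#'   (default `Ep - Eprime - eps_I`).
#' @param phi Azimuth (radians); sampled uniformly when `NULL`.
#' @return List with `theta`, `phi`, `dir_electron`, `dir_proton`,
#'   `residual_momentum` (3-vector, eV/c, given to the target) and `clamped`.
#' @export
electron_emission_kinematics <- function(Ep, Eprime, eps_I, dir_p = c(0, 0, 1),
                                         Ep_after = Ep - Eprime - eps_I,
                                         phi = NULL) {
  stopifnot(Ep > 0, Eprime >= 0)
  Emax <- 4 * .me_over_mp * Ep
  clamped <- Eprime >= Emax
  ct <- sqrt(min(Eprime / Emax, 1))
  if (is.null(phi)) phi <- stats::runif(1, 0, 2 * pi)
  dir_e <- if (clamped) dir_p else .rotate_direction(dir_p, ct, phi)
  p_i <- sqrt(2 * .const$mp_eV * Ep)
  p_e <- sqrt(2 * .const$me_eV * Eprime)
  bal <- p_i * dir_p - p_e * dir_e
  nb <- sqrt(sum(bal^2))
  dir_p_new <- if (nb > 0) bal / nb else dir_p
  p_p_after <- sqrt(2 * .const$mp_eV * max(Ep_after, 0))
  residual <- bal - p_p_after * dir_p_new
  list(theta = acos(ct), phi = phi, dir_electron = dir_e,
       dir_proton = dir_p_new, residual_momentum = residual,
       clamped = clamped)
}
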