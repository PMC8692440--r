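# R-level driver around the compiled engine.

.xs_pack <- function(xs) {
  list(lEp = xs$lEp, Sig_tot = xs$Sig_tot, Stot = xs$Stot, Lkin = xs$Lkin,
       Lpot = xs$Lpot, eps = xs$eps, shell_cum = xs$shell_cum,
       lEs = log(xs$Es), cdf = xs$cdf)
}

#' Transport protons event by event
#'
#' Runs `histories` independent proton histories through one of the
#' supported geometries, spawning and (optionally) transporting secondary
#' electrons, and returns raw tally output plus a per-history energy audit.
#' Each history uses its own counter-derived random stream, so results are
#' independent of execution order.
#'
#' @param material A `protrax_material`.
#' @param E0 Beam kinetic energy (eV).
#' @param geometry One of:
#'   `list(type="box", side_nm=)` closed reflective box (conservation runs);
#'   `list(type="slab", zmax_nm=)` projected-range column;
#'   `list(type="thin_slab", zmax_nm=)` secondary-electron spectrum target;
#'   `list(type="cylinder", thickness_nm=, radial_edges=)` radial dose;
#'   `list(type="sphere_lattice", R_nm=, nlat=, angle_max_deg=)` lineal energy.
#' @param histories Number of primaries.
#' @param seed Integer seed.
#' @param electrons Transport secondary electrons (default TRUE).
#' @param cut Cut policy: `list(frac = 0.005)` kills the proton after losing
#'   that fraction of its energy (remainder discarded); `list(threshold =
#'   eV)` stops it at an energy threshold (remainder deposited locally).
#' @param xs Optional prebuilt `protrax_xs` table (else built on the fly).
#' @param electron_model An [electron_xs_set()].
#' @param record_events Keep the deposit-event list (capped).
#' @param max_events Per-history electron event guard.
#' @return List: engine tallies (see `src/transport.cpp`), `balance` (relative
#'   per-history energy residuals), and the inputs used.
#' @export
transport_proton <- function(material, E0, geometry, histories = 1L,
                             seed = 1L, electrons = TRUE,
                             cut = list(), xs = NULL,
                             electron_model = electron_xs_set(),
                             record_events = FALSE, max_events = 1e6,
                             local_electrons = FALSE) {
  if (is.null(xs)) xs <- build_xs_table(material)
  run <- list(E0 = E0, local_electrons = local_electrons,
              histories = as.integer(histories),
              seed = as.integer(seed), electrons = electrons,
              record_events = record_events, max_record = 5e5,
              max_events = max_events,
              frac_cut = if (!is.null(cut$frac)) cut$frac else 0,
              deposit_remainder = is.null(cut$frac))
  if (!is.null(cut$threshold)) run$eth_cut <- cut$threshold
  gtype <- geometry$type
  if (gtype == "box") {
    run$mode <- 0L; run$L <- geometry$side_nm
  } else if (gtype == "slab") {
    run$mode <- 1L; run$zmax <- geometry$zmax_nm
  } else if (gtype == "thin_slab") {
    run$mode <- 2L; run$zmax <- geometry$zmax_nm
  } else if (gtype == "cylinder") {
    run$mode <- 3L; run$thick <- geometry$thickness_nm
    run$radial_edges <- if (!is.null(geometry$radial_edges))
      geometry$radial_edges else radial_edges_default()
  } else if (gtype == "sphere_lattice") {
    run$mode <- 4L
    run$R_sphere <- geometry$R_nm
    run$nlat <- if (!is.null(geometry$nlat)) as.integer(geometry$nlat) else 179L
    run$L <- run$R_sphere * run$nlat
    run$angle_max_deg <- if (!is.null(geometry$angle_max_deg))
      geometry$angle_max_deg else 0
    run$cell_score <- isTRUE(geometry$cell_score)
  } else {
    stop("unknown geometry type '", gtype, "'", call. = FALSE)
  }
  res <- cpp_run(.xs_pack(xs), .emodel_pack(electron_model, material), run)
  acc <- res$dep_total_hist + res$escaped_hist + res$discarded_hist +
    res$banked_hist
  res$balance <- (res$E_in - acc) / res$E_in
  res$run <- run
  res$material <- material$name
  if (res$overflow > 0) {
    warning(res$overflow, " electron cascade(s) hit the event guard; ",
            "their remaining energy was deposited locally", call. = FALSE)
  }
  res
}
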