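# Canned benchmark configurations and the run driver: secondary-electron
# spectra (a), projected range (b), radial dose (c), lineal energy (d).

.benchmark_types <- c("sdcs", "range", "radial", "lineal")

#' Build a benchmark run configuration
#'
#' Returns the canned configuration of one of the four benchmarks, with
#' overridable fields.  All cutoffs, geometries and defaults follow the
#' validation setups described in the package vignette.
#'
#' @param type One of `"sdcs"`, `"range"`, `"radial"`, `"lineal"`.
#' @param energy_MeV Beam energy.
#' @param material Material name: `"water"`, `"teg"`, or a material config
#'   list understood by [load_material()].
#' @param histories Number of primaries.
#' @param seed Integer seed.
#' @param ... Type-specific overrides: `R_nm` and `angle_max_deg` (lineal),
#'   `thickness_nm` (radial/sdcs), `zmax_cm` (range), `frac_cut`,
#'   `density`.
#' @return A validated config list of class `protrax_config`.
#' @export
benchmark_config <- function(type, energy_MeV, material = "water",
                             histories = NULL, seed = 1L, ...) {
  type <- match.arg(type, .benchmark_types)
  ov <- list(...)
  cfg <- switch(type,
    sdcs = list(
      # thin dense target: 1e24 atoms/cm^3 (water: /3 molecules), 10 nm
      thickness_nm = 10, density = 1e24 / 3 * 18.015 / 6.02214076e23,
      histories = 1e4, electrons = FALSE),
    range = list(
      zmax_cm = 500, density = 1, histories = 200, electrons = FALSE,
      threshold_eV = 1e3),
    radial = list(
      thickness_nm = 100, density = 1, histories = 100, frac_cut = 0.001,
      electrons = TRUE),
    lineal = list(
      R_nm = 360, nlat = 179, angle_max_deg = 30, density = 1,
      histories = 200, frac_cut = 0.005, electrons = TRUE, ymax = 10))
  cfg$type <- type
  cfg$energy_MeV <- energy_MeV
  cfg$material <- material
  cfg$seed <- as.integer(seed)
  if (!is.null(histories)) cfg$histories <- histories
  for (f in names(ov)) cfg[[f]] <- ov[[f]]
  cfg$histories <- as.integer(cfg$histories)
  class(cfg) <- "protrax_config"
  validate_config(cfg)
  cfg
}

#' @rdname benchmark_config
#' @param cfg A config list.
#' @export
validate_config <- function(cfg) {
  bad <- character(0)
  chk <- function(cond, what) if (!isTRUE(cond)) bad <<- c(bad, what)
  chk(is.character(cfg$type) && cfg$type %in% .benchmark_types, "type")
  chk(is.numeric(cfg$energy_MeV) && cfg$energy_MeV > 0, "energy_MeV")
  chk(is.numeric(cfg$histories) && cfg$histories >= 1, "histories")
  chk(is.numeric(cfg$seed), "seed")
  chk(is.numeric(cfg$density) && cfg$density > 0, "density")
  if (!is.null(cfg$frac_cut)) chk(cfg$frac_cut > 0, "frac_cut")
  if (!is.null(cfg$threshold_eV)) chk(cfg$threshold_eV > 0, "threshold_eV")
  if (cfg$type == "lineal") chk(is.numeric(cfg$R_nm) && cfg$R_nm > 0, "R_nm")
  if (length(bad)) {
    stop("invalid benchmark config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(cfg)
}

.config_material <- function(cfg) {
  if (is.list(cfg$material)) return(load_material(cfg$material))
  switch(tolower(cfg$material),
         water = material_water(cfg$density),
         teg = material_teg(cfg$density),
         stop("unknown material name '", cfg$material, "'", call. = FALSE))
}

#' Read / write a benchmark configuration (JSON)
#' @param path File path.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  cfg$histories <- as.integer(cfg$histories)
  class(cfg) <- "protrax_config"
  validate_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param cfg A `protrax_config`.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# stable FNV-1a hash of the serialized config, for provenance
.config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run a benchmark end to end
#'
#' Builds the material and cross-section tables, runs the transport engine,
#' and finalizes the benchmark's tally.  Deterministic for a given
#' (config, seed).
#'
#' @param cfg A `protrax_config` from [benchmark_config()] or
#'   [read_run_config()].
#' @param out Optional output directory; tallies are written as CSV and the
#'   summary as JSON.
#' @param xs Optional prebuilt cross-section table (rebuilt otherwise).
#' @return List with `summary` (named scalars incl. provenance) and
#'   type-specific tally data.
#' @export
run_benchmark <- function(cfg, out = NULL, xs = NULL) {
  validate_config(cfg)
  mat <- .config_material(cfg)
  if (is.null(xs)) xs <- build_xs_table(mat)
  E0 <- cfg$energy_MeV * 1e6
  type <- cfg$type

  geometry <- switch(type,
    sdcs = list(type = "thin_slab", zmax_nm = cfg$thickness_nm),
    range = list(type = "slab", zmax_nm = cfg$zmax_cm * 1e7),
    radial = list(type = "cylinder", thickness_nm = cfg$thickness_nm),
    lineal = list(type = "sphere_lattice", R_nm = cfg$R_nm, nlat = cfg$nlat,
                  angle_max_deg = cfg$angle_max_deg))
  cut <- list()
  if (!is.null(cfg$frac_cut)) cut$frac <- cfg$frac_cut
  if (!is.null(cfg$threshold_eV)) cut$threshold <- cfg$threshold_eV

  res <- transport_proton(mat, E0, geometry, histories = cfg$histories,
                          seed = cfg$seed, electrons = isTRUE(cfg$electrons),
                          cut = cut, xs = xs)

  summary <- list(type = type, material = mat$name,
                  energy_MeV = cfg$energy_MeV, histories = cfg$histories,
                  seed = cfg$seed, config_hash = .config_hash(cfg),
                  version = as.character(utils::packageVersion("protrax")),
                  energy_balance_max = max(abs(res$balance)))
  tally <- list()

  if (type == "range") {
    summary$mean_range_cm <- mean(res$range_z) * 1e-7
    summary$sd_range_cm <- stats::sd(res$range_z) * 1e-7
    tally$range_cm <- res$range_z * 1e-7
  } else if (type == "sdcs") {
    spec <- sdcs_spectrum_tally(res$births, cfg$histories,
                                mat$number_density, cfg$thickness_nm * 1e-7)
    summary$ionisations_per_proton <- attr(spec, "ionisations_per_proton")
    tally$spectrum <- spec
  } else if (type == "radial") {
    edges <- res$run$radial_edges
    prof <- radial_dose_finalize(res$radial_E, edges, cfg$thickness_nm,
                                 cfg$density, cfg$histories)
    summary$total_energy_eV <- attr(prof, "total_energy")
    tally$radial <- prof
  } else if (type == "lineal") {
    fin <- lineal_energy_finalize(res$y, ymax = cfg$ymax, already_y = TRUE)
    summary$y_F <- fin$y_F
    summary$y_D <- fin$y_D
    summary$y_D_restricted <- fin$y_D_restricted
    summary$n_events <- fin$n_events
    tally$fy <- fin$fy
    tally$y <- res$y
  }

  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (nm in names(tally)) {
      obj <- tally[[nm]]
      if (is.data.frame(obj)) {
        utils::write.csv(obj, file.path(out, paste0(nm, ".csv")),
                         row.names = FALSE)
      } else {
        utils::write.csv(data.frame(value = obj),
                         file.path(out, paste0(nm, ".csv")), row.names = FALSE)
      }
    }
  }
  c(list(summary = summary), tally,
    list(balance = res$balance, flags = list(floored = res$floored_steps,
                                             clamped = res$clamped,
                                             overflow = res$overflow)))
}
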