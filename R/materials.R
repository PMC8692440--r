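# Target material construction: composition -> number densities, electron
# shells with ionisation potentials, and Rudd parameter-set assignment.

#' Parse an empirical chemical formula
#'
#' @param species Formula string such as `"C3H8"`, `"H2O"` or `"Fe"`.
#' @return Named numeric vector of element counts.
#' @export
parse_formula <- function(species) {
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", species)) {
    stop("cannot parse species formula '", species, "'", call. = FALSE)
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", species)[[1]]
  toks <- regmatches(species, list(m))[[1]]
  counts <- numeric(0)
  for (tk in toks) {
    el <- sub("[0-9]*$", "", tk)
    k <- sub("^[A-Za-z]+", "", tk)
    k <- if (nzchar(k)) as.numeric(k) else 1
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0) + k
  }
  bad <- setdiff(names(counts), names(.atomic_weights))
  if (length(bad)) {
    stop("unknown element(s) in '", species, "': ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts
}

# canonical registry key: elements in alphabetical order with counts
formula_key <- function(species) {
  counts <- parse_formula(species)
  counts <- counts[order(names(counts))]
  paste0(names(counts), counts, collapse = "")
}

.registry_keys <- NULL
.registry_lookup <- function(key) {
  keys <- vapply(names(.molecule_registry), formula_key, "")
  hit <- names(keys)[keys == key]
  if (length(hit)) hit[[1]] else NA_character_
}

.species_molar_mass <- function(species) {
  counts <- parse_formula(species)
  sum(counts * .atomic_weights[names(counts)])
}

.species_electrons <- function(species) {
  counts <- parse_formula(species)
  sum(counts * .atomic_numbers[names(counts)])
}

# Shells of one species (per molecule), with parameter-set assignment.
.species_shells <- function(species) {
  key <- formula_key(species)
  regname <- .registry_lookup(key)
  if (!is.na(regname)) {
    reg <- .molecule_registry[[regname]]
    sh <- reg$shells
    pset <- vapply(seq_len(nrow(sh)), function(i) {
      assign_rudd_parameters(as.list(sh[i, ]), regname)
    }, "")
    return(data.frame(species = species, subshell = sh$subshell, eps = sh$eps,
                      occ = sh$occ, pset = pset, stringsAsFactors = FALSE))
  }
  counts <- parse_formula(species)
  if (length(counts) > 1 || any(counts != 1)) {
    warning("no molecular ionisation-potential data for '", species,
            "'; decomposing into constituent atoms (may overestimate cross ",
            "sections)", call. = FALSE)
  }
  out <- lapply(names(counts), function(el) {
    sh <- element_shells(el)
    pset <- vapply(seq_len(nrow(sh)), function(i) {
      assign_rudd_parameters(as.list(sh[i, ]), el)
    }, "")
    data.frame(species = species, subshell = paste0(el, ":", sh$subshell),
               eps = sh$eps, occ = sh$occ * counts[[el]], pset = pset,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Define a target material
#'
#' Builds the full material description used by the cross-section and
#' transport machinery: mixture number density, electron shells (ionisation
#' potential, occupancy, Rudd parameter set) and electron density.
#' Compounds with a bundled molecular orbital structure (H2O, CO2, CH4, H2,
#' O2) use molecular shells; other compounds decompose into their
#' constituent atoms with a warning.
#'
#' @param config A list with fields `name`, `density` (g/cm^3) and
#'   `constituents`, a list of `list(species=, fraction=)` entries with molar
#'   fractions summing to 1.  Optional: `number_density` (formula units per
#'   cm^3) to override the value derived from the mass density, and
#'   `shell_overrides`, a list of `list(species=, subshell=, eps=, occ=,
#'   pset=)` partial overrides.
#' @return An object of class `protrax_material`.
#' @examples
#' m <- load_material(list(name = "water", density = 1,
#'                         constituents = list(list(species = "H2O", fraction = 1))))
#' m$number_density   # ~3.34e22 molecules/cm^3
#' @export
load_material <- function(config) {
  stopifnot(is.list(config), !is.null(config$constituents))
  dens <- config$density
  if (is.null(dens) || dens <= 0) stop("material density must be positive", call. = FALSE)
  sp <- vapply(config$constituents, function(x) x$species, "")
  fr <- vapply(config$constituents, function(x) as.numeric(x$fraction), 0)
  if (any(fr <= 0)) stop("molar fractions must be positive", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("molar fractions sum to ", format(sum(fr)), ", not 1", call. = FALSE)
  }

  mm <- vapply(sp, .species_molar_mass, 0)
  M_mix <- sum(fr * mm)
  n <- if (!is.null(config$number_density)) {
    as.numeric(config$number_density)
  } else {
    dens * .const$Na / M_mix
  }

  shells <- do.call(rbind, lapply(seq_along(sp), function(i) {
    sh <- .species_shells(sp[i])
    sh$weight <- fr[i]
    sh
  }))
  shells <- .apply_shell_overrides(shells, config$shell_overrides)
  shells$eff_occ <- shells$occ * shells$weight

  e_density <- n * sum(shells$eff_occ)

  out <- structure(list(
    name            = if (!is.null(config$name)) config$name else paste(sp, collapse = "+"),
    constituents    = data.frame(species = sp, fraction = fr, molar_mass = mm,
                                 row.names = NULL),
    mass_density    = dens,
    molar_mass      = M_mix,
    number_density  = n,
    shells          = shells,
    electron_density = e_density,
    stopping        = .stopping_components(sp, fr, mm, M_mix)
  ), class = "protrax_material")
  out
}

.apply_shell_overrides <- function(shells, overrides) {
  if (is.null(overrides)) return(shells)
  for (ov in overrides) {
    idx <- shells$species == ov$species & shells$subshell == ov$subshell
    if (!any(idx)) {
      stop("shell override targets unknown shell ", ov$species, "/",
           ov$subshell, call. = FALSE)
    }
    for (f in intersect(names(ov), c("eps", "occ", "pset"))) {
      shells[[f]][idx] <- ov[[f]]
    }
  }
  shells
}

# Per-component (Z/A, I) decomposition for Bragg-additive stopping.
# Registry molecules with a compound I-value stay one component; everything
# else decomposes into elements.
.stopping_components <- function(sp, fr, mm, M_mix) {
  comp <- list()
  for (i in seq_along(sp)) {
    w_total <- fr[i] * mm[i] / M_mix        # mass fraction of the species
    key <- formula_key(sp[i])
    regname <- .registry_lookup(key)
    Imol <- if (!is.na(regname)) .molecule_registry[[regname]]$I_eV else NA_real_
    if (!is.na(Imol)) {
      Z <- .species_electrons(sp[i])
      comp[[length(comp) + 1L]] <- data.frame(
        component = sp[i], mass_fraction = w_total, zoa = Z / mm[i], I_eV = Imol)
    } else {
      counts <- parse_formula(sp[i])
      for (el in names(counts)) {
        w_el <- w_total * counts[[el]] * .atomic_weights[[el]] / mm[i]
        comp[[length(comp) + 1L]] <- data.frame(
          component = el, mass_fraction = w_el,
          zoa = .atomic_numbers[[el]] / .atomic_weights[[el]],
          I_eV = .ivalues[[el]])
      }
    }
  }
  comp <- do.call(rbind, comp)
  # merge duplicate components
  agg <- stats::aggregate(mass_fraction ~ component + zoa + I_eV, comp, sum)
  agg[order(-agg$mass_fraction), c("component", "mass_fraction", "zoa", "I_eV")]
}

#' @export
print.protrax_material <- function(x, ...) {
  cat("<protrax_material> ", x$name, "\n", sep = "")
  cat(sprintf("  density %.4g g/cm^3, n = %.4g /cm^3, ne = %.4g e/cm^3\n",
              x$mass_density, x$number_density, x$electron_density))
  cat(sprintf("  %d shells over %d constituent(s)\n",
              nrow(x$shells), nrow(x$constituents)))
  invisible(x)
}

#' Convert mass fractions to molar fractions
#'
#' @param species Character vector of formulas.
#' @param mass_fractions Numeric vector summing to 1.
#' @return Named numeric vector of molar fractions.
#' @export
molar_from_mass_fractions <- function(species, mass_fractions) {
  stopifnot(length(species) == length(mass_fractions))
  if (abs(sum(mass_fractions) - 1) > 1e-9) {
    stop("mass fractions must sum to 1", call. = FALSE)
  }
  mm <- vapply(species, .species_molar_mass, 0)
  x <- mass_fractions / mm
  stats::setNames(x / sum(x), species)
}

#' Liquid water material
#' @param density Mass density in g/cm^3 (default 1).
#' @export
material_water <- function(density = 1.0) {
  load_material(list(name = "water", density = density,
                     constituents = list(list(species = "H2O", fraction = 1))))
}

#' Tissue-equivalent gas (propane based), at arbitrary density
#'
#' Molar composition 54.7% C3H8, 39.7% CO2, 5.6% N2.  The microdosimetric
#' benchmarks use it at unit density so that nm-scale site sizes in the gas
#' emulate the tissue sites probed by a proportional counter.
#'
#' @param density Mass density in g/cm^3 (default 1).
#' @export
material_teg <- function(density = 1.0) {
  suppressWarnings(load_material(list(
    name = "TEG", density = density,
    constituents = list(list(species = "C3H8", fraction = 0.547),
                        list(species = "CO2", fraction = 0.397),
                        list(species = "N2", fraction = 0.056)))))
}

#' Read / write a material configuration (JSON)
#'
#' The on-disk schema mirrors the `load_material()` input: fields `name`,
#' `density`, `constituents` (array of `{species, fraction}`), optional
#' `number_density` and `shell_overrides`.
#'
#' @param path File path.
#' @export
read_material_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  load_material(cfg)
}

#' @rdname read_material_config
#' @param config The list form of the configuration (not the built material).
#' @export
write_material_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
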