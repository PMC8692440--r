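Package: protrax
Title: Event-by-Event Proton Track-Structure Simulation for Arbitrary Materials
Version: 0.1.0
Authors@R:
    person("Track Structure", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Event-by-event Monte Carlo simulation of proton tracks in
    arbitrary materials without dielectric-function data.  Ionisation is
    sampled from Rudd-model singly-differential cross sections per electron
    shell, while the overall energy budget is constrained by a total
    stopping-power model (restricted stopping-power bookkeeping): the
    non-ionising energy loss is the total stopping power minus the mean
    ionising loss computed from the cross-section integrals.  Secondary
    electrons are transported event by event down to 1 eV with
    electron-density scaling of a reference water cross-section set.
    Includes microdosimetric tallies: secondary-electron spectra, projected
    range, radial dose profiles, and lineal-energy distributions
    (f(y), y_F, y_D) on a sphere lattice.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
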