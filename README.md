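# protrax

Event-by-event proton track-structure Monte Carlo for **arbitrary
materials**, in R with a compiled (Rcpp) transport core.

Conventional track-structure codes need the dielectric function of the
target, which is only well measured for liquid water.  `protrax` instead
combines two ingredients that exist for essentially any material:

* **Rudd-model singly-differential ionisation cross sections (SDCS)** per
  electron shell, `dσ/dE' = (S/ε)·[F1(v) + F2(v)w] / [(1+w)³(1+e^{α(w−w_c)/v})]`
  with `w = E'/ε`, `v² = (m_e/m_p)E_p/ε`, `S = 4πa₀²N(Ry/ε)²` — these
  decide *where* ionisations happen and what secondary-electron energy `E'`
  is ejected; and
* a **total stopping power** `S_tot(E)` (Bethe above 0.5 MeV, a
  velocity-proportional branch below the ~80 keV maximum, Bragg additivity
  for compounds) — this fixes the overall energy budget.

The two are reconciled by *restricted stopping-power bookkeeping*: along a
free flight `dL = −ln r / Σ_ion(E_p)` the proton continuously deposits the
**non-ionising** part

```
dE_non = S_tot·dL − n Σ_i ∫ (ε_i + E') σ_i(E', E_p) dE' dL
```

and at the collision it pays the sampled shell's ionisation potential
`ε_I` (deposited at the point) plus the sampled `E'` (carried away by the
electron).  Averaged along the track, `dE/dx` equals `S_tot` exactly, while
every ionisation is simulated explicitly.  Secondary electrons are
transported event by event down to 1 eV with a replaceable reference water
cross-section set, scaled to the target by electron density.

Tallies cover the standard validation surface: secondary-electron spectra,
projected range, radial dose profiles, and microdosimetric lineal-energy
distributions `f(y)` with frequency/dose means `y_F`, `y_D` on a
simple-cubic sphere lattice (`y = ε / ((2/3)·d)` for sphere diameter `d`).

## Worked example

```r
library(protrax)

teg <- material_teg()                       # 54.7% C3H8 + 39.7% CO2 + 5.6% N2, 1 g/cm^3
total_stopping_power(teg, 30e6, "keV/um")
#> [1] 1.908                                # LET of a 30 MeV proton in TEG

w <- material_water()
macroscopic_ionisation_xs(w, 1e6)           # Sigma_ion, 1 MeV proton
#> [1] 4332000                              # 1/cm  => mean free path 2.31 nm

mean_ionising_loss_rate(w, 1e6)$total * 1e-7
#> [1] 28.19                                # keV/um carried by ionisation
csda_range(w, 1e7)
#> [1] 0.1214                               # cm, 10 MeV CSDA range

# microdosimetry: 30 MeV protons crossing a cube of 179^3 spheres (d = 360 nm)
xs <- build_xs_table(teg)
m <- transport_proton(teg, 30e6,
        list(type = "sphere_lattice", R_nm = 360, nlat = 179, angle_max_deg = 30),
        histories = 50, seed = 1, cut = list(frac = 0.005), xs = xs)
fin <- lineal_energy_finalize(m$y, ymax = 10, already_y = TRUE)
c(y_F = fin$y_F, y_D = fin$y_D, events = fin$n_events)
#>      y_F      y_D   events
#>     1.55     4.48  7017.00
```

`y_F` sits near the 1.3–1.9 keV/μm LET scale (part of each crossing's
energy is exported by delta rays); `y_D` is pulled upward by rare spheres
that absorb an energetic secondary electron.  See the methods vignette
(`vignettes/track-structure.Rmd`) for what the dose-mean does — and does
not — reproduce, and why.

Benchmarks can also be driven from config files / the CLI:

```sh
Rscript inst/cli/protrax run --config inst/configs/lineal_teg_360nm.json \
        --seed 7 --histories 200 --out out/
Rscript inst/cli/protrax stopping --material teg --out teg_stopping.csv
```

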