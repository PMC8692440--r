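---
title: "Restricted stopping-power track structure: model, assumptions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restricted stopping-power track structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(protrax)
```

## The model

`protrax` simulates proton tracks event by event, resolving every
ionisation, in materials for which no dielectric-function data exist.  Two
independent, widely available ingredients are combined:

1. **Per-shell ionisation cross sections** from the nine-parameter Rudd
   model.  For a shell with ionisation potential $\varepsilon$ and
   occupancy $N$, with scaled ejection energy $w = E'/\varepsilon$ and
   scaled speed $v^2 = (m_e/m_p)E_p/\varepsilon$,
   $$\frac{d\sigma}{dE'} = \frac{S}{\varepsilon}\,
     \frac{F_1(v) + F_2(v)\,w}{(1+w)^3\,\bigl(1 + e^{\alpha(w - w_c)/v}\bigr)},
     \qquad S = 4\pi a_0^2 N \left(\frac{\mathrm{Ry}}{\varepsilon}\right)^2,$$
   with cutoff $w_c = 4v^2 - 2v - \mathrm{Ry}/(4\varepsilon)$.  The
   $1/\varepsilon^3$ prefactor makes the outermost shells dominant, which
   is why a noble-gas analogy per shell (K-like outer shells use the He
   fit, L→Ne, M→Ar, N→Kr; a generic set for inner shells) is adequate for
   arbitrary elements.
2. **A total stopping power** $S_\mathrm{tot}(E)$: Bethe above 0.5 MeV
   with ICRU-style mean excitation energies and Bragg additivity,
   a velocity-proportional ($\propto\sqrt{E}$) branch below the
   $\sim$80 keV maximum, and $C^1$ log–log Hermite bridges between.

Between ionisations the proton flies
$dL = -\ln r/\Sigma_\mathrm{ion}(E_p)$ and *continuously* deposits the
non-ionising remainder
$$dE_\mathrm{non} = S_\mathrm{tot}\,dL - n\sum_i\int_0^\infty
   (\varepsilon_i + E')\,\sigma_i(E',E_p)\,dE'\,dL,$$
i.e. everything (elastic recoil, excitation, vibrations) that is not
explicit ionisation.  At the collision the sampled shell's potential
$\varepsilon_I$ is deposited at the point and the electron carries $E'$.
The track-averaged energy loss therefore equals $S_\mathrm{tot}$ by
construction (verified to <1% in the test suite), while the spatial
structure of ionisation is explicit.

Emission kinematics are non-relativistic binary collisions:
$\cos^2\theta = E'/E'_\mathrm{max}$, $E'_\mathrm{max}=4(m_e/m_p)E_p$,
uniform azimuth; the proton direction follows from momentum balance and
any unbalanced momentum (forward-clamped emissions) is booked to the
target atom.  At 30 MeV ($\beta\approx0.25$) the relativistic correction
to $E'_\mathrm{max}$ is under 2%.

### Bookkeeping edge cases

The two ingredients are independent fits, so the mean ionising rate can
*exceed* $S_\mathrm{tot}$ (in our water model by up to ~4% around 1 MeV).
The bookkeeping then lets the proton energy rise slightly along a flight —
the ionisation potential repays it at the collision.  Deposits, however,
are never negative: the floored-away amount is subtracted from the next
collision-point deposit, keeping per-history conservation exact (tested at
$10^{-6}$ relative).  In the rare case (<0.1% of sub-MeV steps) where a
long flight's gain would exceed the collision cost, the excess is deposited
at the collision point so the proton energy is strictly decreasing across
collisions, as the physical argument requires.

## Electron transport

Secondary electrons and their cascades are transported event by event to a
1 eV cutoff with a *replaceable* analytic reference set for water, scaled
to any target by electron density (macroscopic cross sections multiply by
$n_e^\mathrm{target}/n_e^\mathrm{water}$; the scaling is exact by
construction and verified statistically):

* **elastic** — screened Rutherford (Molière screening, $Z=10$), scaled by
  0.4 with a $T/(T+150\,\mathrm{eV})$ damping.  Raw screened-Rutherford
  magnitudes overshoot condensed-phase elastic data several-fold at
  0.1–1 keV; the damping removes the unphysical low-energy divergence.
* **ionisation** — binary-encounter-Bethe on the five water orbitals
  (binding 12.61, 14.73, 18.55, 32.2, 539.7 eV); the secondary energy
  follows the $1/(W+B)^2$ binary-encounter shape up to $(T-B)/2$;
  daughters are emitted at the binary-encounter angle
  $\cos\theta_d=\sqrt{W/(W+B)}$ and transported depth-first (LIFO —
  no physics consequence, fixed for reproducibility).
* **excitation** — one lumped electronic level: threshold 7.4 eV, mean
  loss 10 eV, Massey-peak shape with scale $4\times10^{-16}$ cm².
* **vibrational** — flat $0.5\times10^{-16}$ cm² below 30 eV, 0.4 eV per
  event, so sub-excitation electrons random-walk down to the 1 eV cutoff
  instead of stalling below the electronic thresholds.

The free constants were set once against two stated anchors — the ~20 nm,
nearly energy-independent excursion of 3–300 eV electrons in unit-density
water (we obtain a mean of ~18 nm over that range) and realistic
liquid-water elastic magnitudes — *before* any microdosimetric quantity
was computed, and were not revisited afterwards.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| proton-energy grid | 1 keV–1 GeV, 32/decade | — | SDCS varies smoothly in $\log E_p$ |
| ejection-energy grid | $10^{-3}$ eV–10 MeV, 64/decade | — | resolves both the sub-eV rise and the Rutherford tail; a 0.1 eV floor was measurably biased (1.6% of the spectrum) |
| electron cutoff | 1 | eV | transport contract; below it energy is deposited at the point (the real electron thermalises within a few nm) |
| proton termination | 1 | keV | stopping/cross-section table floor; the residual range below it (~10 nm in water) is far below every tally resolution |
| continuous-deposit sub-step | 10 | nm | spatial resolution of the non-ionising deposit along flights |
| lineal-energy site | $d$ = 360 or 1440 | nm | sphere diameter; $y=\varepsilon/((2/3)d)$ |
| proton cut (microdosimetry) | 0.5% energy loss | — | samples the track at fixed LET; remainder discarded, electrons still followed |
| proton cut (radial dose) | 0.1% energy loss | — | same idea at fixed beam energy |

Every history owns a counter-derived RNG stream (`splitmix64`-seeded
xoshiro256+), so results are independent of execution order and any
history can be reproduced in isolation.

## Numerical choices

* **Quadrature.** The SDCS spans ~10 decades of ejection energy with its
  mass near $E'\sim\varepsilon$.  A plain adaptive pass over the raw
  interval silently missed that peak (20% low against a $2\times10^6$-point
  trapezoid oracle); the quadrature ops integrate the bulk on a log scale.
  The transport tables never depended on this: they integrate on the fine
  log grid directly, and the test suite compares both routes against the
  brute-force oracle.
* **Sampling.** Inverse transform on tabulated CDFs, linear in
  (probability, $\log E'$), with a stochastic choice between the two
  bracketing proton-energy nodes.  The tabulated first moment is defined
  as the mean the *sampler* realises, so the restricted bookkeeping and
  the sampled energies agree without discretisation bias.
* **Lineal-energy moments** are computed from the raw event list, not from
  the histogram; the histogram (20 bins/decade) is for export/plots only.

## What the synthetic benchmarks establish — and what they do not

The four bundled benchmarks are idealised geometries: a 10 nm dense target
(first-generation electron spectra), a 500 cm water column (projected
range), a 100 nm reflective-capped cylinder (radial dose), and a
reflective cube of $179^3$ touching spheres (lineal energy).  They exercise
the full transport chain, and the green property suite establishes:
energy conservation per history; strict energy decrease across collisions;
track-averaged $dE/dx = S_\mathrm{tot}$ (the model's central
self-consistency claim); exponential flight statistics; sampling/quadrature
agreement (KS at 1%); projected ranges on the CSDA integral within 5%;
a delta-ray halo falling like $r^{-2.3}$ with >80% of the 1 MeV dose
inside 10 nm; $f(y)$ normalisation and $y_D \ge y_F$; and a delta-ray
yield above 2.4 keV within 9% of the Rutherford close-collision limit.

They do **not** establish absolute dose-mean lineal energies.  With the
bundled electron engine the computed $y_D$ for 30 MeV protons lands
~20–30% below the reference values (TEG, 360 nm spheres: ~4.7–5.4 vs 7.56
keV/μm; water: ~4.8–5.6 vs 7.17; TEG 1440 nm restricted: ~2.8–3.1 vs
4.09).  The diagnostics bracket the cause tightly: the single-collision
spectrum is right (Rutherford-limit tail, correct $y\!\cdot\!f(y)$ peak
position at 1.3 keV/μm, at-or-above reference level at $y=10$), and a
deposit-at-birth bound shows $y_D$ would reach ~24 if secondary-electron
energy stayed at its origin — so the dose mean is controlled almost
entirely by how compactly the external-grade electron engine re-localises
cascade energy at the sub-sphere scale, precisely the component this
package deliberately stands in for behind an interface.  Two geometric
conventions the reference leaves open also move the result: scoring
interstitial deposits to the nearest sphere (`cell_score = TRUE`) raises
$y_D$ by ~0.6–0.7 keV/μm.  We keep the conservative defaults
(simple-cubic touching spheres, interstitial energy unscored,
`cell_score = FALSE`) and report the gap rather than tuning the electron
model toward the target numbers.

## Open points, resolved as design choices

* *Sphere packing*: simple-cubic lattice of touching spheres; deposits in
  the interstitial 48% of the volume count toward energy balance but not
  toward any sphere.  The nearest-sphere alternative is exposed as
  `cell_score`.
* *Beam incidence (microdosimetry)*: polar angle uniform on [0°, 30°]
  from the inward surface normal, uniform azimuth.
* *Occupancy placement*: shell occupancy lives inside $\sigma_i$; molar
  fractions weight shells of mixtures.
* *Proton recoil*: the direction update from momentum balance is applied
  (it is conservation-consistent) although negligible at benchmark
  energies; no additional angular-straggling model exists in this scheme.
* *Config format*: JSON (round-trip tested) rather than YAML, to stay
  within guaranteed-available dependencies.

## Known limitations

No Auger relaxation (inner-shell vacancies deposit their potential
locally); no nuclear stopping channel, charge exchange, or molecular-bond
and crystalline corrections; non-relativistic kinematics (fine to
~50 MeV); per-gas Rudd fit parameters for Ne, Ar, Kr, O₂, CO₂ and CH₄ are
synthetic stand-ins reusing the water shape parameters (see
`R/rudd-parameters.R`) — magnitudes are still material-specific through
$\varepsilon^{-3}$, occupancy and the kinematic cutoff; the electron
engine is a simplified stand-in whose absolute microdosimetric
concentration is the dominant model-transfer uncertainty, as quantified
above.
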