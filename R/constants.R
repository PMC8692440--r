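# Physical constants (CODATA 2018). Energies in eV, lengths in cm unless noted.
.const <- list(
  Na        = 6.02214076e23,     # 1/mol
  a0_cm     = 5.29177210903e-9,  # Bohr radius
  Ry        = 13.605693122994,   # Rydberg energy, eV
  me_eV     = 0.51099895000e6,   # electron rest mass, eV/c^2
  mp_eV     = 938.27208816e6,    # proton rest mass, eV/c^2
  re_cm     = 2.8179403262e-13,  # classical electron radius
  K_bethe   = 0.307075,          # 4 pi Na re^2 me c^2 / u, MeV cm^2/g (per Z/A)
  mec2_MeV  = 0.51099895,
  mpc2_MeV  = 938.27208816,
  four_pi_a0sq = 4 * pi * 5.29177210903e-9^2  # cm^2
)

# mass ratio used by the binary-collision kinematics and the Rudd scaled speed
.me_over_mp <- .const$me_eV / .const$mp_eV
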