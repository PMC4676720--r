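# Default shielding-model parameter set.
# Units are explicit per field; concentrations are converted to molar on load.
params:
  psi_mV: -25          # local electrostatic potential at the substrate, millivolts
  temperature_K: 295.15 # room temperature
  L_ref_mM: 32          # half-maximal effective cation concentration, divalent anchor
  z_ref: 2              # valence at which L_ref is anchored (Mg2+)
  pip2_total_uM: 30     # total substrate (PIP2 analog) concentration
  W_uM: 0               # unshieldable residual substrate (neomycin fits override)
  Kd_uM: 50             # effective enzyme-substrate dissociation constant

cations:
  Mg:
    z: 2
    "Y": 1
    K_per_M: 1          # association constant on the effective-concentration scale
  Ca:
    z: 2
    "Y": 1
    K_per_M: 190
  Ba:
    z: 2
    "Y": 1
    K_per_M: 460
  putrescine:
    z: 2
    "Y": 0.12
    K_per_M: 0.2778     # 1 / 3600 mM
  spermidine:
    z: 3
    "Y": 0.12
    K_per_M: 52.63      # 1 / 19 mM
  spermine:
    z: 4
    "Y": 0.12
    K_per_M: 100        # 1 / 10 mM
  neomycin:
    z: 6
    "Y": 0.12
    K_per_M: 1000       # 1 / 1 mM
    W_uM: 4.1           # plateau of unshieldable substrate seen only with neomycin
    plateau_capable: true
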