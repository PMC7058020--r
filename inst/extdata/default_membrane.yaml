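# Reference Lo/Ld membrane parameter set.
# Moduli quoted in mN/m are converted internally with kBT = 4e-21 J
# (1 mN/m = 0.25 kBT/nm^2).
kBT_joules: 4.0e-21
sigma0: 0.025          # lateral tension per monolayer, kBT/nm^2
phase_r:               # liquid-ordered
  B: 20                # splay modulus, kBT
  Kt_mN_per_m: 40      # tilt modulus
  Ka_mN_per_m: 120     # stretching modulus
  J0: 0                # spontaneous curvature, 1/nm
  h: 1.8               # hydrophobic monolayer thickness, nm
phase_s:               # liquid-disordered
  B: 10
  Kt_mN_per_m: 40
  Ka_mN_per_m: 120
  J0: 0
  h: 1.3
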