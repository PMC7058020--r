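# W(X0) scan for an intermediate-thickness lipid stripe at L = +3 nm.
membrane: default
solver:
  dx: 0.025
  half_width: 15
scan:
  kind: inclusion_position
  L: 3
  X0_from: -12
  X0_to: 12
  step: 0.25
inclusion:
  family: lipid_stripe
  h0: 1.55             # stripe monolayer thickness, nm
  J0: 0                # stripe spontaneous curvature, 1/nm
  B0: 10               # stripe splay modulus, kBT
  deltaL: 1.3          # stripe width, nm
output_dir: stripe_out
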