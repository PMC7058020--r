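# W(L) scan of the bare domain boundary with the reference membrane.
membrane: default
solver:
  dx: 0.025            # grid spacing, nm
  half_width: 20       # box margin beyond outermost structure, nm
scan:
  kind: boundary_shift
  L_from: -6
  L_to: 6
  step: 0.25
output_dir: boundary_out
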