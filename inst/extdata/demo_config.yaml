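# Demo: 20-residue chain, proline at position 10, fully sampled resolved
# grids, noiseless. Expect 100 % forward and backward link recovery.
sequence: "MDVFMKGLSPAKEGVVAAAE"
seed: 42
experiment: HACACONCOCONH_5D
field_mhz: 600
axes:
  n_anchor: 32
  n_resolved: 64
n_points: 4096
snr: 0
tol:
  CO: 0.12
  N: 0.5
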