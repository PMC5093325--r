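# FF-style concentration-series experiment: strongly asymmetric nanotube
# (all exchange on the fast O face), open bath, frame-sampled with
# 5-replicate averaged position reads.
concentrations_mM: [1.60, 2.40, 2.80, 3.20, 3.60]
n_tubes: 10
duration_min: 10
seed: 1
filament:
  preset: ff
  layer_um: 0.01
  initial_length_um: 30
measurement:
  sigma_um: 0.25
  n_repeats: 5
  frame_interval_min: 0.5
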