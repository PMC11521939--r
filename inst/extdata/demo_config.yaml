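# Demo configuration: one acetone-like (single dominant receptor) odorant at
# 100 ppm, compressed protocol, desk-scale calyx.
n_receptors: 23
n_kc: 500
q: 6
dt: 2.0e-5
t_total: 0.8
stimulus:
  t_on: 0.1
  t_off: 0.7
odorants:
  - profile: sparse
    k: 1
    seed: 7
    amplitude: 100
threshold: 0.5
seeds:
  graph: 1
  noise: 1
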