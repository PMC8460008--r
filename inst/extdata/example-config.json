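{
  "m": 1,
  "gamma": 0.1,
  "mu": 0.01,
  "k_cells": 50,
  "b0": 0.01,
  "sigma": 0,
  "k_total": 20000,
  "nu": 0,
  "s": 0.02,
  "n": 0.98,
  "n_groups": 20,
  "t_max": 1500,
  "seed": 1
}
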