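# The published worked evaluation: explicit (global) indicator weights,
# first-level weights, and expert-scored membership matrices. Evaluated in
# "global" mode: global weights at the group stage, first-level weights
# applied again, normalization absorbing the double weighting.
evaluation_levels: [none, mild, moderate, severe, extreme]
mode: global
weights:
  first_level: [0.54, 0.35, 0.11]
  groups:
    environmental: [0.39, 0.11, 0.05]
    physiological: [0.14, 0.05, 0.03, 0.13]
    behavioral: [0.06, 0.03, 0.02, 0.01]
membership:
  environmental:
    - [0, 1, 0, 0, 0]
    - [0, 0.9, 0.1, 0, 0]
    - [1, 0, 0, 0, 0]
  physiological:
    - [1, 0, 0, 0, 0]
    - [0.8, 0.2, 0, 0, 0]
    - [0.7, 0.3, 0, 0, 0]
    - [1, 0, 0, 0, 0]
  behavioral:
    - [0.8, 0.2, 0, 0, 0]
    - [0.9, 0.1, 0, 0, 0]
    - [0.6, 0.4, 0, 0, 0]
    - [1, 0, 0, 0, 0]
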