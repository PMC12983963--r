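# Expert-panel judgment matrices (upper triangles; reciprocals are
# completed exactly at load time).
evaluation_levels: [none, mild, moderate, severe, extreme]
mode: global
panels:
  expert:
    first_level:
      labels: [environmental, physiological, behavioral]
      upper: [4, 3, 2]
    groups:
      environmental:
        labels: [temperature_c, humidity_pct, wind]
        upper: [2, 5, 3]
      physiological:
        labels: [weight_kg, height_cm, diagonal_cm, chest_cm]
        upper: [2, 3, 3, 2, 3, 2]
      behavioral:
        labels: [lying_min, standing_min, rr_per_min, urination_n]
        upper: [2, 2, 2, 3, 4, 2]
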