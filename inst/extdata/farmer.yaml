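# Farmer-panel judgment matrices (upper triangles). The physiological
# matrix is not fully consistent (CR above 0.10 by the column-normalization
# method), so this document loads only with `allow_inconsistent = TRUE`.
evaluation_levels: [none, mild, moderate, severe, extreme]
mode: global
panels:
  farmer:
    first_level:
      labels: [environmental, physiological, behavioral]
      upper: [2, 4, 4]
    groups:
      environmental:
        labels: [temperature_c, humidity_pct, wind]
        upper: [5, 7, 3]
      physiological:
        labels: [weight_kg, height_cm, diagonal_cm, chest_cm]
        upper: [3, 5, 2, 2, 3, 3]
      behavioral:
        labels: [lying_min, standing_min, rr_per_min, urination_n]
        upper: [3, 3, 4, 2, 3, 2]
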