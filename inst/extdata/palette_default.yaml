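# Default jersey palette: white (light) Team A vs navy (dark) Team B.
team_a:
  label: A
  rgb: [255, 255, 255]
team_b:
  label: B
  rgb: [0, 0, 128]
match_threshold: 25      # CIELAB Delta-E gate for stage-1 reference matching
lightness_split: 50      # stage-2 fallback: L* above -> light team
lightness_band: 5        # dead band around the split -> unknown
min_pixels: 25           # smaller mask supports are classified unknown
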