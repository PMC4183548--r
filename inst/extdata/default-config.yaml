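# Shipped defaults for collagenquant runs. Every threshold is on the 8-bit
# hue/saturation/brightness scale; all bounds inclusive.
bins:
  red:    {h_lo: 1,  h_hi: 13,  s_lo: 10, s_hi: 255, b_lo: 20, b_hi: 255}
  orange: {h_lo: 14, h_hi: 25,  s_lo: 10, s_hi: 255, b_lo: 20, b_hi: 255}
  yellow: {h_lo: 26, h_hi: 52,  s_lo: 10, s_hi: 255, b_lo: 20, b_hi: 255}
  green:  {h_lo: 53, h_hi: 110, s_lo: 10, s_hi: 255, b_lo: 20, b_hi: 255}
blue_range: {h_lo: 121, h_hi: 179, s_lo: 20, s_hi: 255, b_lo: 10, b_hi: 255}
white_cut: 230        # brightfield pixels at/above this brightness ...
min_sat: 25           # ... and at/below this saturation are empty/lumen
dark_quantile: 0.25   # darkest fraction used for background estimation
aggregation: patient  # or "core"
reference_group: null # group whose normalized proportions average to 1
seed: 1
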