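{
  "description": "3-layer validation sphere: scalp/skull/brain conductivities at DC, opposed polar-cap current injection",
  "radii_mm": [92, 85, 78],
  "labels": ["scalp", "skull", "gray_matter"],
  "frequency_Hz": 0,
  "cap_half_angle_deg": 20,
  "current_A": 0.001,
  "legendre_order": 60,
  "spacing_mm": 2
}
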