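{
  "radii": {
    "scalp": 92,
    "skull": 85,
    "csf": 78,
    "gm": 75,
    "wm": 60
  },
  "spacing": 2,
  "tumor": {
    "center": [15, 0, 0],
    "r_core": 12,
    "t_shell": 6
  },
  "defect": {
    "diameter": 50,
    "axis_center": {},
    "side": {}
  },
  "montage": "LR",
  "array": {
    "pitch": 30,
    "transducer_radius": 10,
    "transducer_height": 1,
    "gel_radius": 12.5,
    "gel_thickness": 1,
    "active_side": 1,
    "jitter_sd": 0,
    "seed": {}
  }
}
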