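[
  {
    "label": "artery",
    "shape": "circle",
    "center": [32, 9],
    "radius": 4
  },
  {
    "label": "tumor",
    "shape": "rectangle",
    "bounds": [36, 32, 16, 16]
  },
  {
    "label": "white_matter",
    "shape": "polygon",
    "vertices": [[6, 26], [6, 55], [14, 57], [24, 50], [22, 28]]
  }
]
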