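{
  "_comment": "Reference-numbered region map (1-based, inclusive intervals, descendant/ConI numbering). Boundary coordinates are editable defaults chosen for the synthetic stand-in alignment: the published boundaries appear only graphically and are not machine-readable here. All code takes this map as input; nothing is hard-coded.",
  "reference": "ConI numbering (synthetic stand-in)",
  "regions": {
    "NT": [1, 14],
    "L2": [26, 33],
    "L3": [36, 42],
    "L4": [44, 50],
    "L5": [70, 78],
    "L6": [86, 93],
    "CT": [110, 136]
  }
}
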