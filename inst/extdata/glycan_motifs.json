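{
  "_comment": "Structural motif annotations for the lacto-series glycans compared in the specificity analysis. Motif sets are reconstructed from the printed pairwise 'different structure' column; #41/#42 differ only in core linkage (lacto-N- vs lacto-N-neo-), which is below this motif vocabulary. The printed #47 vs #43 difference (alpha1,2-fucosyl(Gal)) is inconsistent with the other printed rows; the set reconstruction yields alpha1,3-GalNAc(Gal) for that pair.",
  "glycans": {
    "41": [],
    "42": [],
    "43": ["alpha1,2-fucosyl(Gal)"],
    "44": ["alpha1,4-fucosyl(GlcNAc)"],
    "45": ["alpha1,3-fucosyl(GlcNAc)"],
    "46": ["alpha1,2-fucosyl(Gal)", "alpha1,4-fucosyl(GlcNAc)"],
    "47": ["alpha1,2-fucosyl(Gal)", "alpha1,3-GalNAc(Gal)"],
    "48": ["alpha1,4-fucosyl(GlcNAc)", "alpha1,2-fucosyl(Gal)", "alpha1,3-GalNAc(Gal)"]
  }
}
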