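glycan_a,glycan_b,Con-anc-N/C/L5,Con-anc-N/C/L5/L6,Con-anc-N/C/L5/L6/L3,different_structures
45,41,2.48,2.48,0.9,"alpha1,3-fucosyl(GlcNAc)"
43,42,1.01,1.11,1.29,"alpha1,2-fucosyl(Gal)"
44,42,6.18,5.27,1.89,"alpha1,4-fucosyl(GlcNAc)"
46,42,10.7,8.76,2.02,"alpha1,2-fucosyl(Gal)/alpha1,4-fucosyl(GlcNAc)"
47,42,1.62,1.55,1.63,"alpha1,2-fucosyl(Gal)/alpha1,3-GalNAc(Gal)"
48,42,16.2,11.4,2.71,"alpha1,4-fucosyl(GlcNAc)/alpha1,2-fucosyl(Gal)/alpha1,3-GalNAc(Gal)"
46,43,10.6,7.91,1.57,"alpha1,4-fucosyl(GlcNAc)"
46,44,1.73,1.66,1.07,"alpha1,2-fucosyl(Gal)"
47,43,1.61,1.4,1.27,"alpha1,2-fucosyl(Gal)"
48,43,16.1,10.3,2.1,"alpha1,4-fucosyl(GlcNAc)/alpha1,3-GalNAc(Gal)"
48,46,1.52,1.3,1.34,"alpha1,3-GalNAc(Gal)"
48,47,10,7.34,1.66,"alpha1,4-fucosyl(GlcNAc)"
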