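>ConI synthetic stand-in, descendant galectin, reference numbering source
VDHDQLNCCDSTMFPHEQESPYEREHGRLSICEPEFITQPWENTIRRVMKRNERRRRKQGLTFEPYISPMNSTLKGDNLKPIKLNQRLFIFKMLKCYSEGQVCEEATHMHRTIMYDPFGPWNNGQHKHWEFLMHIF
>ConII synthetic stand-in, paralogue (135 aa, demo only)
ECQDQLYCCDVTMFPHEQESPYEREHGRFIICVLEFITQHWENTIRRHPKRHECRRRKQGLTFEPYDSPMNCTLSGDN-KPIKLNRRLFIFKMWKDNSRGQVCQEATHEHITIDYDPQGGWNNPQTKHWEFLMHIF
>Con-anc synthetic stand-in, reconstructed ancestor (134 aa, 31 sites differ from ConI)
VDHDELNCCDSKMFPSEQEGPYEHEHGRLSTCEHEFIMQPWEFTIRRVMVRNERRSRKQWLTFMPYIVPLNSMVNS--LLPIKINQKLTIFMMLECYSEVQVCEEATHMHRTIMYDPAGNWNNGQHKHWEFFMHIF
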