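ligand	ki_nM	delta_g
UK-432097	4	-11.45
UK-432097	4.75	-11.35
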