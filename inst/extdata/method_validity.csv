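preparation,detection,measurand
Kn,flow,protein
Cm,flow,protein
FISH,flow,protein
HCR,flow,protein
FISH,flow,rna_fluorescence
HCR,flow,rna_fluorescence
FISH,microscopy,protein
HCR,microscopy,protein
FISH,microscopy,rna_fluorescence
HCR,microscopy,rna_fluorescence
FISH,microscopy,rna_count
HCR,microscopy,rna_count
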