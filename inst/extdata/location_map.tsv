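raw	canonical
cytoplasm	cytoplasm
cytosol	cytoplasm
cytoskeleton	cytoskeleton
endoplasmic reticulum	endoplasmic reticulum
endoplasmic reticulum membrane	endoplasmic reticulum
extracellular	extracellular
secreted	extracellular
extracellular space	extracellular
golgi	golgi
golgi apparatus	golgi
membrane	membrane
cell membrane	membrane
plasma membrane	membrane
mitochondria	mitochondria
mitochondrion	mitochondria
nucleus	nucleus
nuclear	nucleus
transmembrane	transmembrane
single-pass membrane protein	transmembrane
multi-pass membrane protein	transmembrane
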