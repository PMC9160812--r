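gene	locations
KRT18	Cytoplasm;Intermediate filaments
KRT8	Cytoplasm;Intermediate filaments
NAPSA	Cytoplasm;Vesicles
MUC1	Membrane;Secreted
WFDC2	Cytoplasm
SFTPB	Cytoplasm;Vesicles
HOPX	Nucleus;Cytoplasm
KRT7	Cytoplasm;Intermediate filaments
EPCAM	Membrane
KRT19	Cytoplasm;Intermediate filaments
SFTA2	Cytoplasm
ZFP36L1	Nucleus;Cytoplasm
ERRFI1	Cytoplasm
C8ORF4	Cytoplasm
ELF3	Nucleus
NKX2-1	Membrane;Nucleus
RNASE1	Cytoplasm
GPRC5A	Membrane
CLDN4	Membrane;Cell Junctions
SLC34A2	Membrane
IRX2	Nucleus
CAPN8	Cytoplasm
SPINK13	Secreted
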