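gene	species
CCND1	Md
CCNE1	Me
CCNA2	Ma
CCNB1	Mb
MIRLET7C	Let7
PTEN	PTEN
IL6	IL6
NFKB1	NFKB
STAT3	STAT3
MIR21	miR21
LIN28A	Lin28
KRAS	Ras
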