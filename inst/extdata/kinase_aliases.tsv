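alias	symbol
ERBB1	EGFR
HER2	ERBB2
NEU	ERBB2
HER3	ERBB3
HER4	ERBB4
ABL	ABL1
ARG	ABL2
P38A	MAPK14
P38B	MAPK11
ERK1	MAPK3
ERK2	MAPK1
JNK1	MAPK8
JNK2	MAPK9
JNK3	MAPK10
MEK1	MAP2K1
MEK2	MAP2K2
MEK7	MAP2K7
AURORA-A	AURKA
AURORA-B	AURKB
VEGFR2	KDR
VEGFR1	FLT1
VEGFR3	FLT4
TRKA	NTRK1
TRKB	NTRK2
TRKC	NTRK3
FAK	PTK2
PYK2	PTK2B
ACK1	TNK2
CSK21	CSNK2A1
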