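# Accessible-cysteine kinase whitelist (synthetic reconstruction):
# 208 human kinase gene symbols representing kinases with a
# cysteine accessible from the ATP pocket. One symbol per line.
EGFR
ERBB2
ERBB3
ERBB4
BTK
BMX
ITK
TEC
TXK
BLK
JAK1
JAK2
JAK3
TYK2
FGFR1
FGFR2
FGFR3
FGFR4
SRC
YES1
FGR
FYN
LCK
HCK
LYN
FRK
ABL1
ABL2
KIT
PDGFRA
PDGFRB
FLT1
FLT3
FLT4
KDR
RET
MET
MST1R
ALK
LTK
ROS1
INSR
IGF1R
INSRR
DDR1
DDR2
EPHA1
EPHA2
EPHA3
EPHA4
EPHA5
EPHA6
EPHA7
EPHA8
EPHB1
EPHB2
EPHB3
EPHB4
TYRO3
AXL
MERTK
TNK1
TNK2
PTK2
PTK2B
PTK6
SYK
ZAP70
FES
FER
CSF1R
MUSK
NTRK1
NTRK2
NTRK3
TIE1
TEK
ROR1
RYK
BRAF
RAF1
ARAF
IRAK1
IRAK4
LIMK1
LIMK2
TESK1
TESK2
BMPR1A
BMPR1B
BMPR2
ACVR1
ACVR1B
ACVR2A
ACVR2B
TGFBR1
TGFBR2
MAP3K7
ANKK1
LRRK2
RIPK1
RIPK2
RIPK3
MAP2K1
MAP2K2
MAP2K3
MAP2K4
MAP2K5
MAP2K6
MAP2K7
MAP3K1
MAP3K2
MAP3K3
MAP3K5
MAP3K8
MAP3K9
MAP3K11
MAP4K1
MAP4K2
MAP4K3
MAP4K4
MAP4K5
PAK1
PAK2
PAK4
STK3
STK4
STK10
STK24
STK26
SLK
TAOK1
TAOK2
TAOK3
MINK1
TNIK
CDK1
CDK2
CDK4
CDK5
CDK6
CDK7
CDK8
CDK9
CDK12
CDK13
MAPK1
MAPK3
MAPK7
MAPK8
MAPK9
MAPK10
MAPK11
MAPK12
MAPK13
MAPK14
MAPK15
GSK3A
GSK3B
DYRK1A
DYRK1B
DYRK2
CLK1
CLK2
CLK3
CLK4
HIPK1
HIPK2
SRPK1
SRPK2
NLK
CAMK1
CAMK2A
CAMK2B
CAMK2D
CAMK2G
CAMK4
CHEK1
CHEK2
MKNK1
MKNK2
MELK
MARK1
MARK2
MARK3
MARK4
PIM1
PIM2
PIM3
DAPK1
DAPK2
DAPK3
STK11
BRSK1
BRSK2
NUAK1
NUAK2
SIK1
SIK2
SIK3
PRKD1
PRKD2
PRKD3
PHKG1
PHKG2
AKT1
AKT2
AKT3
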