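# Human protein-kinase gene symbols (editable reference list, one per line).
# Used only to restrict kinase-substrate tables to kinase-kinase edges;
# supply your own list via the kinome= argument to override.
AATK
ABL1
ABL2
ACVR1
ACVR1B
ACVR1C
ACVR2A
ACVR2B
ACVRL1
ADCK1
ADCK2
AKT1
AKT2
AKT3
ALK
ALPK1
ALPK2
ALPK3
AMHR2
ANKK1
ARAF
ATM
ATR
AURKA
AURKB
AURKC
AXL
BCKDK
BLK
BMPR1A
BMPR1B
BMPR2
BMX
BRAF
BRSK1
BRSK2
BTK
BUB1
BUB1B
CAMK1
CAMK1D
CAMK1G
CAMK2A
CAMK2B
CAMK2D
CAMK2G
CAMK4
CAMKK1
CAMKK2
CASK
CDC42BPA
CDC42BPB
CDC42BPG
CDC7
CDK1
CDK2
CDK3
CDK4
CDK5
CDK6
CDK7
CDK8
CDK9
CDK10
CDK11A
CDK11B
CDK12
CDK13
CDK14
CDK15
CDK16
CDK17
CDK18
CDK19
CDK20
CDKL1
CDKL2
CDKL3
CDKL4
CDKL5
CHEK1
CHEK2
CHUK
CIT
CLK1
CLK2
CLK3
CLK4
COQ8A
COQ8B
CSF1R
CSK
CSNK1A1
CSNK1A1L
CSNK1D
CSNK1E
CSNK1G1
CSNK1G2
CSNK1G3
CSNK2A1
CSNK2A2
DAPK1
DAPK2
DAPK3
DCLK1
DCLK2
DCLK3
DDR1
DDR2
DMPK
DSTYK
DYRK1A
DYRK1B
DYRK2
DYRK3
DYRK4
EEF2K
EGFR
EIF2AK1
EIF2AK2
EIF2AK3
EIF2AK4
EPHA1
EPHA2
EPHA3
EPHA4
EPHA5
EPHA6
EPHA7
EPHA8
EPHA10
EPHB1
EPHB2
EPHB3
EPHB4
EPHB6
ERBB2
ERBB3
ERBB4
FER
FES
FGFR1
FGFR2
FGFR3
FGFR4
FGR
FLT1
FLT3
FLT4
FRK
FYN
GAK
GRK1
GRK2
GRK3
GRK4
GRK5
GRK6
GRK7
GSG2
GSK3A
GSK3B
HCK
HIPK1
HIPK2
HIPK3
HIPK4
HUNK
ICK
IGF1R
IKBKB
IKBKE
ILK
INSR
INSRR
IRAK1
IRAK2
IRAK3
IRAK4
ITK
JAK1
JAK2
JAK3
KDR
KIT
KSR1
KSR2
LATS1
LATS2
LCK
LIMK1
LIMK2
LMTK2
LMTK3
LRRK1
LRRK2
LTK
LYN
MAK
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
MAP3K4
MAP3K5
MAP3K6
MAP3K7
MAP3K8
MAP3K9
MAP3K10
MAP3K11
MAP3K12
MAP3K13
MAP3K14
MAP3K15
MAP3K19
MAP3K20
MAP3K21
MAP4K1
MAP4K2
MAP4K3
MAP4K4
MAP4K5
MAPK1
MAPK3
MAPK4
MAPK6
MAPK7
MAPK8
MAPK9
MAPK10
MAPK11
MAPK12
MAPK13
MAPK14
MAPK15
MAPKAPK2
MAPKAPK3
MAPKAPK5
MARK1
MARK2
MARK3
MARK4
MAST1
MAST2
MAST3
MAST4
MASTL
MATK
MELK
MERTK
MET
MINK1
MKNK1
MKNK2
MOK
MOS
MST1R
MTOR
MUSK
MYLK
MYLK2
MYLK3
MYLK4
MYO3A
MYO3B
NEK1
NEK2
NEK3
NEK4
NEK5
NEK6
NEK7
NEK8
NEK9
NEK10
NEK11
NIM1K
NLK
NRK
NTRK1
NTRK2
NTRK3
NUAK1
NUAK2
OBSCN
OXSR1
PAK1
PAK2
PAK3
PAK4
PAK5
PAK6
PASK
PBK
PDGFRA
PDGFRB
PDK1
PDK2
PDK3
PDK4
PDPK1
PHKG1
PHKG2
PIM1
PIM2
PIM3
PKMYT1
PKN1
PKN2
PKN3
PLK1
PLK2
PLK3
PLK4
PNCK
PRKAA1
PRKAA2
PRKACA
PRKACB
PRKACG
PRKCA
PRKCB
PRKCD
PRKCE
PRKCG
PRKCH
PRKCI
PRKCQ
PRKCZ
PRKD1
PRKD2
PRKD3
PRKDC
PRKG1
PRKG2
PRKX
PRKY
PRPF4B
PTK2
PTK2B
PTK6
PTK7
RAF1
RET
RIOK1
RIOK2
RIOK3
RIPK1
RIPK2
RIPK3
RIPK4
ROCK1
ROCK2
ROR1
ROR2
ROS1
RPS6KA1
RPS6KA2
RPS6KA3
RPS6KA4
RPS6KA5
RPS6KA6
RPS6KB1
RPS6KB2
RPS6KC1
RPS6KL1
RYK
SBK1
SBK2
SBK3
SGK1
SGK2
SGK3
SIK1
SIK2
SIK3
SLK
SMG1
SNRK
SPEG
SRC
SRMS
SRPK1
SRPK2
SRPK3
STK3
STK4
STK10
STK11
STK16
STK17A
STK17B
STK24
STK25
STK26
STK31
STK32A
STK32B
STK32C
STK33
STK35
STK36
STK38
STK38L
STK39
STK40
STYK1
SYK
TAOK1
TAOK2
TAOK3
TBK1
TEC
TEK
TESK1
TESK2
TGFBR1
TGFBR2
TIE1
TLK1
TLK2
TNIK
TNK1
TNK2
TNNI3K
TRIO
TRPM6
TRPM7
TSSK1B
TSSK2
TSSK3
TSSK4
TSSK6
TTBK1
TTBK2
TTK
TTN
TXK
TYK2
TYRO3
ULK1
ULK2
ULK3
ULK4
VRK1
VRK2
VRK3
WEE1
WEE2
WNK1
WNK2
WNK3
WNK4
YES1
ZAP70
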