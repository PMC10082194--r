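# Synthetic placeholder subset of widely recognised cancer gene census
# symbols, bundled so the gene-restriction filter is runnable out of the box.
# Replace with a full licensed census export for production analyses.
ABL1
AKT1
ALK
APC
ARID1A
ARID1B
ARID2
ASXL1
ATM
ATR
ATRX
AXIN1
BAP1
BARD1
BCL2
BCOR
BRAF
BRCA1
BRCA2
BRIP1
CARD11
CASP8
CBL
CCND1
CCNE1
CDH1
CDK12
CDK4
CDK6
CDKN1B
CDKN2A
CEBPA
CHEK2
CIC
CREBBP
CTCF
CTNNB1
DAXX
DDX3X
DICER1
DNMT3A
EGFR
EP300
ERBB2
ERBB3
ERCC2
ESR1
EZH2
FANCA
FANCC
FANCD2
FBXW7
FGFR1
FGFR2
FGFR3
FLT3
FOXA1
GATA1
GATA3
GNA11
GNAQ
GNAS
HNF1A
HRAS
IDH1
IDH2
JAK1
JAK2
JAK3
KDM5C
KDM6A
KDR
KEAP1
KIT
KMT2A
KMT2C
KMT2D
KRAS
MAP2K1
MAP2K4
MAP3K1
MDM2
MDM4
MED12
MEN1
MET
MLH1
MPL
MSH2
MSH6
MTOR
MYC
MYCL
MYCN
MYD88
NBN
NCOR1
NF1
NF2
NFE2L2
NOTCH1
NOTCH2
NPM1
NRAS
NTRK1
NTRK3
ORC1
PALB2
PBRM1
PDGFRA
PIK3CA
PIK3R1
PMS2
POLE
PPP2R1A
PTCH1
PTEN
PTPN11
RAD21
RAD51B
RAD51C
RAD51D
RB1
RET
RNF43
ROS1
RUNX1
SETD2
SF3B1
SMAD2
SMAD4
SMARCA4
SMARCB1
SMO
SOCS1
SPOP
STAG2
STK11
TET2
TP53
TSC1
TSC2
U2AF1
VHL
WT1
XRCC2
XRCC3
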