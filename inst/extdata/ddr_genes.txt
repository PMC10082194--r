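# DNA-damage-response gene list (editable; assembled from genes annotated to
# DNA damage checkpoint, telomere maintenance, DNA replication, DNA repair,
# translesion synthesis, double-strand-break and radiation-response processes).
# Replace with your own list for production use; one symbol per line.
ATM
ATR
ATRIP
BARD1
BLM
BRCA1
BRCA2
BRIP1
CDC6
CDK12
CDT1
CHEK1
CHEK2
CLSPN
DCLRE1C
DDB1
DDB2
DNA2
EXO1
ERCC1
ERCC2
ERCC3
ERCC4
ERCC5
ERCC6
ERCC8
FANCA
FANCB
FANCC
FANCD2
FANCE
FANCF
FANCG
FANCI
FANCL
FANCM
FEN1
GEN1
H2AFX
HELQ
HUS1
LIG1
LIG3
LIG4
MBD4
MCM2
MCM3
MCM4
MCM5
MCM6
MCM7
MDC1
MLH1
MLH3
MNAT1
MRE11A
MSH2
MSH3
MSH6
MUTYH
NBN
NEIL1
NEIL2
NEIL3
NHEJ1
NTHL1
OGG1
ORC1
ORC2
ORC3
ORC4
ORC5
ORC6
PALB2
PARP1
PARP2
PAXIP1
PCNA
PMS1
PMS2
POLA1
POLB
POLD1
POLE
POLH
POLI
POLK
POLM
POLN
POLQ
POT1
PRIM1
PRKDC
RAD1
RAD17
RAD18
RAD21
RAD23A
RAD23B
RAD50
RAD51
RAD51B
RAD51C
RAD51D
RAD52
RAD54B
RAD54L
RAD9A
RBBP8
RECQL
RECQL4
RECQL5
REV1
REV3L
RFC1
RFC2
RFC3
RFC4
RFC5
RMI1
RMI2
RNASEH2A
RPA1
RPA2
RPA3
RTEL1
SLX1A
SLX4
SMC1A
SMC3
TERF1
TERF2
TERT
TINF2
TIMELESS
TIPIN
TOP3A
TOPBP1
TP53
TP53BP1
TREX1
UBE2T
UNG
USP1
WEE1
WRN
XPA
XPC
XRCC1
XRCC2
XRCC3
XRCC4
XRCC5
XRCC6
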