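symbol	trait
APOB	Low-density lipoprotein
APOC2	Low-density lipoprotein
APOE	Low-density lipoprotein
LDLR	Low-density lipoprotein
LPL	Low-density lipoprotein
PCSK9	Low-density lipoprotein
ABCA1	High-density lipoprotein
APOA1	High-density lipoprotein
CETP	High-density lipoprotein
LIPC	High-density lipoprotein
LIPG	High-density lipoprotein
PLTP	High-density lipoprotein
SCARB1	High-density lipoprotein
ANTXR1	Height
ATR	Height
BLM	Height
CDC6	Height
CDT1	Height
CENPJ	Height
COL1A1	Height
COL1A2	Height
COMP	Height
CREBBP	Height
DNA2	Height
EP300	Height
EVC	Height
EVC2	Height
FBN1	Height
FGFR3	Height
FKBP10	Height
HR	Height
KRAS	Height
NBN	Height
NIPBL	Height
ORC1	Height
ORC4	Height
ORC6L	Height
PCNT	Height
PLOD2	Height
PTPN11	Height
RAD21	Height
RAF1	Height
RECQL4	Height
RIT1	Height
ROR2	Height
SLC26A2	Height
SMAD4	Height
SRCAP	Height
WRN	Height
ATG16L1	Crohn disease
CARD9	Crohn disease
IL10	Crohn disease
IL10RA	Crohn disease
IL10RB	Crohn disease
IL23R	Crohn disease
IRGM	Crohn disease
NOD2	Crohn disease
PRDM1	Crohn disease
PTPN22	Crohn disease
ATG16L1	Ulcerative colitis
CARD9	Ulcerative colitis
IL23R	Ulcerative colitis
IRGM	Ulcerative colitis
PRDM1	Ulcerative colitis
PTPN22	Ulcerative colitis
RNF186	Ulcerative colitis
ABCC8	Type II diabetes
BLK	Type II diabetes
CEL	Type II diabetes
EIF2AK3	Type II diabetes
GATA4	Type II diabetes
GATA6	Type II diabetes
GCK	Type II diabetes
GLIS3	Type II diabetes
HNF1A	Type II diabetes
HNF1B	Type II diabetes
HNF4A	Type II diabetes
IER3IP1	Type II diabetes
INS	Type II diabetes
KCNJ11	Type II diabetes
KLF11	Type II diabetes
LMNA	Type II diabetes
NEUROD1	Type II diabetes
NEUROG3	Type II diabetes
PAX4	Type II diabetes
PDX1	Type II diabetes
PPARG	Type II diabetes
PTF1A	Type II diabetes
RFX6	Type II diabetes
SLC19A2	Type II diabetes
SLC2A2	Type II diabetes
WFS1	Type II diabetes
ZFP57	Type II diabetes
AKT1	Breast cancer
ARID1A	Breast cancer
ATM	Breast cancer
BRCA1	Breast cancer
BRCA2	Breast cancer
CBFB	Breast cancer
CDH1	Breast cancer
CDKN1B	Breast cancer
CHEK2	Breast cancer
CTCF	Breast cancer
ERBB2	Breast cancer
ESR1	Breast cancer
FGFR2	Breast cancer
FOXA1	Breast cancer
GATA3	Breast cancer
GPS2	Breast cancer
HS6ST1	Breast cancer
KMT2C	Breast cancer
KRAS	Breast cancer
LRRC37A3	Breast cancer
MAP2K4	Breast cancer
MAP3K1	Breast cancer
NCOR1	Breast cancer
NF1	Breast cancer
NUP93	Breast cancer
PALB2	Breast cancer
PIK3CA	Breast cancer
PTEN	Breast cancer
RB1	Breast cancer
RUNX1	Breast cancer
SF3B1	Breast cancer
STK11	Breast cancer
TBX3	Breast cancer
TP53	Breast cancer
ZFP36L1	Breast cancer
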