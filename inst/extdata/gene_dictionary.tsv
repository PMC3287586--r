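symbol	synonym
CDX2	CDX2
CDX2	Cdx2
CDX2	Cdx-2
NANOG	NANOG
NANOG	Nanog
POU5F1	POU5F1
POU5F1	Pou5f1
POU5F1	Oct4
POU5F1	Oct-4
POU5F1	OCT4
SOX2	SOX2
SOX2	Sox2
TEAD4	TEAD4
TEAD4	Tead4
YAP1	YAP1
YAP1	Yap
YAP1	Yap1
LATS2	LATS2
LATS2	Lats
LATS2	Lats2
GATA3	GATA3
GATA3	Gata3
TCF3	TCF3
TCF3	Tcf3
NR0B1	NR0B1
NR0B1	Dax1
NR0B1	DAX1
FOXD3	FOXD3
FOXD3	Foxd3
ESRRB	ESRRB
ESRRB	Esrrb
SALL4	SALL4
SALL4	Sall4
KLF4	KLF4
KLF4	Klf4
EOMES	EOMES
EOMES	Eomes
GATA4	GATA4
GATA4	Gata4
GATA6	GATA6
GATA6	Gata6
SOX7	SOX7
SOX7	Sox7
SOX17	SOX17
SOX17	Sox17
FGF4	FGF4
FGF4	Fgf4
LIF	LIF
STAT3	STAT3
STAT3	Stat3
SMAD1	SMAD1
SMAD1	Smad1
BMP4	BMP4
BMP4	Bmp4
MYC	MYC
MYC	c-MYC
MYC	c-Myc
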