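source	target	subtype	evidence
LATS2	YAP1	phosphorylation	demo
YAP1	CDX2	activation	demo
TEAD4	CDX2	activation	demo
TEAD4	GATA3	activation	demo
CDX2	NANOG	inhibition	demo
CDX2	POU5F1	inhibition	demo
NANOG	CDX2	inhibition	demo
POU5F1	CDX2	inhibition	demo
POU5F1	NANOG	activation	demo
SOX2	NANOG	activation	demo
NANOG	POU5F1	activation	demo
POU5F1	POU5F1	activation	demo
SOX2	POU5F1	activation	demo
SALL4	POU5F1	activation	demo
ESRRB	NANOG	activation	demo
KLF4	NANOG	activation	demo
NANOG	FOXD3	activation	demo
FOXD3	POU5F1	activation	demo
POU5F1	POU5F1	inhibition	demo
NR0B1	POU5F1	inhibition	demo
TCF3	POU5F1	inhibition	demo
TCF3	NANOG	inhibition	demo
POU5F1	EOMES	inhibition	demo
POU5F1	FGF4	activation	demo
SOX2	FGF4	activation	demo
NANOG	SMAD1	inhibition	demo
BMP4	CDX2	activation	demo
LIF	STAT3	activation	demo
NANOG	STAT3	activation	demo
SOX7	GATA4	activation	demo
SOX7	GATA6	activation	demo
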