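direction	symbol
up	ALOX5AP
up	BCL2A1
up	CXCR4
up	FCGR3A
up	FOS
up	G0S2
up	GCNT3
up	HIST1H1C
up	HIST1H2BK
up	IL1B
up	IL1R2
up	LITAF
up	OSM
up	PLEK
up	PTGS2
up	RGS2
up	S100A8
up	S100A9
up	SERPINA3
up	TCN1
up	TPM4
down	CAPS
down	CHST9
down	DNALI1
down	MAOB
down	NELL2
down	PPP1R16A
down	PROS1
down	PTGFR
down	RAGE
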