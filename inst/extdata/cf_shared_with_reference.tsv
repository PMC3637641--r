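study	direction	symbol
zabner	up	ACAA2
zabner	up	CDKN2B
zabner	down	IGFBP2
wright	up	C9ORF3
wright	up	KRT14
wright	down	CYP24A1
wright	down	HLA-DQA1
wright	down	SAA4
virella_lowell	up	CAV1
virella_lowell	up	CCNE2
virella_lowell	down	CLGN
virella_lowell	down	ENO2
virella_lowell	down	EPB41L3
virella_lowell	down	GPX3
virella_lowell	down	TIMP4
verhaeghe	up	BCL2A1
verhaeghe	up	G0S2
verhaeghe	up	IL1B
verhaeghe	up	MMP1
verhaeghe	up	RGS2
verhaeghe	down	CKB
verhaeghe	down	CRIP1
verhaeghe	down	CYP24A1
verhaeghe	down	DNALI1
verhaeghe	down	FHL1
verhaeghe	down	GSTT1
verhaeghe	down	IGFBP2
ogilvie	up	BCL2A1
ogilvie	up	G0S2
ogilvie	up	IL1B
ogilvie	up	IL1R2
ogilvie	up	LCP2
ogilvie	up	NDRG1
ogilvie	up	RGS2
ogilvie	up	RNF149
ogilvie	up	TCN1
ogilvie	down	PROS1
ogilvie	down	SCGB1A1
ogilvie	down	SPAG8
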