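gene	role	fc_array	fc_qpcr	efficiency_pct
ADM	target_up	2.9	1.7	100
AQP9	target_up	4.9	1.8	106
AREG	target_up	3.6	1.3	97
GJA1	target_up	3.4	2.7	98
IGFBP3	target_up	2.2	1.2	100
NDRG1	target_up	2.6	2.0	106
TMEM45A	target_up	3.0	1.0	97
SCGB1A1	target_down	-3.3	-2.3	100
SPAG6	target_down	-2.5	-3.4	100
TEKT1	target_down	-3.3	-3.0	103
ACTB	reference	1.2	1.2	100
GAPDH	reference	1.1	0.8	97
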