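study	n_up	n_down
zabner	300	300
wright	300	300
virella_lowell	300	300
verhaeghe	300	300
ogilvie	115	110
clarke	117	220
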