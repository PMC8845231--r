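GO:0007409	axonogenesis	1.2e-4	SHHA,TBX5,NKX2.5,ROBO1,DCC
GO:0007411	axon guidance	3e-3	SHHA,ROBO1,DCC,EPHB2
GO:0060971	embryonic heart tube left/right pattern formation	8e-3	LEFTY1,LEFTY2,PITX2
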