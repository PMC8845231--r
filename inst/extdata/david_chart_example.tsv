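Category	Term	Count	%	PValue	Genes	List Total	Pop Hits	Pop Total	Fold Enrichment	Bonferroni	Benjamini	FDR
GOTERM_BP_DIRECT	GO:0007409~axonogenesis	5	2.1	1.2e-4	SHHA, TBX5, NKX2.5, ROBO1, DCC	200	30	16000	4.2	0.01	0.008	0.01
GOTERM_BP_DIRECT	GO:0007411~axon guidance	4	1.7	3e-3	SHHA, ROBO1, DCC, EPHB2	200	22	16000	3.1	0.1	0.04	0.1
GOTERM_BP_DIRECT	GO:0060971~embryonic heart tube left/right pattern formation	3	1.3	8e-3	LEFTY1, LEFTY2, PITX2	200	12	16000	3.9	0.2	0.06	0.2
KEGG_PATHWAY	hsa04360:Axon guidance	6	2.5	1e-5	A, B, C	200	40	16000	5	0.001	0.0009	0.001
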