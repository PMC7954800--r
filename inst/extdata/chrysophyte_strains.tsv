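species	strain	mode	gc_percent	busco_complete_pct	n50	ploidy
Chromulinospumella sphaerica	JBC27	heterotroph	51.3	21	4039	di
Cornospumella fuschlensis	A-R4-D6	heterotroph	51.7	57	2506	di
Pedospumella encystans	1006	heterotroph	54.5	42	1019	NA
Pedospumella encystans	JBMS11	heterotroph	51.4	62	3876	tetra
Poteriospumella lacustris	JBC07	heterotroph	53.1	69	40792	tri
Poteriospumella lacustris	JBM10	heterotroph	53.1	73	52370	di
Poteriospumella lacustris	JBNZ41	heterotroph	52.9	71	24662	tetra
Spumella vulgaris	199hm	heterotroph	47.9	61	2675	di
Chromulina nebulosa	CCAC 4401B	mixotroph	43.9	42	1694	tri
Dinobryon divergens	FU18K-A	mixotroph	45.1	74	1836	di_or_tri
Dinobryon pediforme	LO226K-S	mixotroph	51.6	31	2530	tri
Epipyxis sp.	PR26K-G	mixotroph	34.1	56	11429	di_or_tetra
Chlorochromonas danica	933-7	mixotroph	45.4	96	97456	tetra
Poterioochromonas malhamensis	DS	mixotroph	40.4	76	22680	tri
Mallomonas annulata	WA18K-M	phototroph	40.1	68	7384	di
Synura sphagnicola	LO234KE	phototroph	46.9	48	2024	di
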