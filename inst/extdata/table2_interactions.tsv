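miRNA	Target Gene	Evidence
hsa-miR-138-5p	RMND5A	validated
hsa-miR-138-5p	ROCK2	validated
hsa-miR-141-3p	ZEB1	validated
hsa-miR-141-3p	MAPK9	validated
hsa-miR-141-3p	HIPK2	validated
hsa-miR-141-3p	PHLPP1	validated
hsa-miR-146-5p	TRAF6	validated
hsa-miR-151-3p	NTRK3	validated
hsa-miR-155-5p	RAB11FIP2	validated
hsa-miR-155-5p	WBP1L	validated
hsa-miR-155-5p	MXI1	validated
hsa-miR-155-5p	PICALM	validated
hsa-miR-155-5p	FLT1	validated
hsa-miR-17-3p	TXRND2	validated
hsa-miR-182-5p	TSC22D3	validated
hsa-miR-182-5p	LRP6	validated
hsa-miR-182-5p	ZEB1	validated
hsa-miR-18a-3p	ATM	validated
hsa-miR-18a-3p	CBX7	validated
hsa-miR-183-5p	LRP6	validated
hsa-miR-19a-3p	CUL5	validated
hsa-miR-19a-3p	MTUS1	validated
hsa-miR-19a-3p	PHLPP1	validated
hsa-miR-200b-3p	ZEB1	validated
hsa-miR-200b-3p	RNF2	validated
hsa-miR-200b-3p	FLT1	validated
hsa-miR-200c-3p	ZEB1	validated
hsa-miR-200c-3p	FLT1	validated
hsa-miR-200c-3p	RNF2	validated
hsa-miR-200c-3p	CFL2	validated
hsa-miR-200c-3p	DUSP1	validated
hsa-miR-200c-3p	KLF9	validated
hsa-miR-200c-3p	CRKL	validated
hsa-miR-200c-3p	ROCK2	validated
hsa-miR-204-3p	PPM1K	validated
hsa-miR-205-5p	PTPRM	validated
hsa-miR-205-5p	LRRK2	validated
hsa-miR-205-5p	ERBB3	validated
hsa-miR-205-5p	CENPF	validated
hsa-miR-205-5p	ZEB1	validated
hsa-miR-21-5p	RPBMS	validated
hsa-miR-21-3p	EGLN1	validated
hsa-miR-21-3p	LRP6	validated
hsa-miR-21-3p	TRL3	validated
hsa-miR-21-3p	DOCK4	validated
hsa-miR-21-3p	SMN1	validated
hsa-miR-21-3p	PCBP1	validated
hsa-miR-223-3p	PTBP2	validated
hsa-miR-223-3p	CYB5A	validated
hsa-miR-223-3p	ATM	validated
hsa-miR-223-3p	CHUCK	validated
hsa-miR-223-3p	PRDM1	validated
hsa-miR-223-3p	ZEB1	validated
hsa-miR-224-5p	PHLPP1	validated
hsa-miR-224-5p	PEBP1	validated
hsa-miR-31-5p	RDX	validated
hsa-miR-381-3p	NFKB1A	validated
hsa-miR-409-3p	RDX	validated
hsa-miR-409-3p	STAG2	validated
hsa-miR-409-3p	ZEB1	validated
hsa-miR-409-3p	CTNND1	validated
hsa-miR-421	ATM	validated
hsa-miR-421	CBX7	validated
hsa-miR-424-3p	LGALS3	validated
hsa-miR-485-3p	SLC40A1	validated
hsa-miR-485-3p	NTRK3	validated
hsa-miR-493-3p	FZD4	validated
hsa-miR-493-3p	MXI1	validated
hsa-miR-501-5p	LAMTOR5	validated
hsa-miR-574-5p	FOXN3	validated
hsa-miR-608	BCL2L1	validated
hsa-miR-629-5p	TRIM33	validated
hsa-miR-652-3p	ZEB1	validated
hsa-miR-760	CSNK2A1	validated
hsa-miR-765	NTRK3	validated
hsa-miR-93-3p	DAB2	validated
hsa-miR-99a-5p	HOXA1	validated
hsa-miR-127-3p	PRDM1	validated
hsa-miR-130b-3p	ZEB1	validated
hsa-miR-130b-3p	SAV1	validated
hsa-miR-130b-3p	CSF1	validated
hsa-miR-130b-3p	CCDC6	validated
hsa-miR-133a-3p	BCL2L1	validated
hsa-miR-133a-3p	PNP	validated
hsa-miR-133a-3p	ZEB1	validated
hsa-miR-133a-3p	UBA2	validated
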