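category	gene_id	printed_count	printed_percent
Unknown	YAR030C	63	29.6
Unknown	MOH1	63	29.6
Unknown	YBL081W	63	29.6
Unknown	YBR206W	63	29.6
Unknown	YBR225W	63	29.6
Unknown	MXR2	63	29.6
Unknown	YCR015C	63	29.6
Unknown	YCR025C	63	29.6
Unknown	YCR102W-A	63	29.6
Unknown	YDL023C	63	29.6
Unknown	YDL034W	63	29.6
Unknown	BSC1	63	29.6
Unknown	YDR015C	63	29.6
Unknown	YDR124W	63	29.6
Unknown	YDR220C	63	29.6
Unknown	PPM1	63	29.6
Unknown	YEL076C	63	29.6
Unknown	JHD1	63	29.6
Unknown	YER137C	63	29.6
Unknown	YER187W	63	29.6
Unknown	THI5	63	29.6
Unknown	ROG3	63	29.6
Unknown	STR3	63	29.6
Unknown	YGL199C	63	29.6
Unknown	YGR018C	63	29.6
Unknown	YGR066C	63	29.6
Unknown	YHL049C	63	29.6
Unknown	CRG1	63	29.6
Unknown	YHR210C	63	29.6
Unknown	YIL082W	63	29.6
Unknown	YIR044C	63	29.6
Unknown	YJL015C	63	29.6
Unknown	YJL135W	63	29.6
Unknown	YJL195C	63	29.6
Unknown	YJL211C	63	29.6
Unknown	HUL4	63	29.6
Unknown	YJR087W	63	29.6
Unknown	YJR107W	63	29.6
Unknown	YJR146W	63	29.6
Unknown	YKL153W	63	29.6
Unknown	YLR236C	63	29.6
Unknown	YLR255C	63	29.6
Unknown	YLR463C	63	29.6
Unknown	BSC3	63	29.6
Unknown	YML002W	63	29.6
Unknown	AIM32	63	29.6
Unknown	YMR013W-A	63	29.6
Unknown	YMR147W	63	29.6
Unknown	YMR294W-A	63	29.6
Unknown	YNL043C	63	29.6
Unknown	YNL057W	63	29.6
Unknown	YNL193W	63	29.6
Unknown	YNL276C	63	29.6
Unknown	BDS1	63	29.6
Unknown	YOR021C	63	29.6
Unknown	YOR041C	63	29.6
Unknown	YOR093C	63	29.6
Unknown	YOR203W	63	29.6
Unknown	YOR248W	63	29.6
Unknown	CIN1	63	29.6
Unknown	YPL113C	63	29.6
Unknown	YPL114W	63	29.6
Unknown	YPR195C	63	29.6
Nucleus	SWD1	61	28.6
Nucleus	CDC27	61	28.6
Nucleus	TKL2	61	28.6
Nucleus	UMP1	61	28.6
Nucleus	TDP1	61	28.6
Nucleus	THI2	61	28.6
Nucleus	SHG1	61	28.6
Nucleus	MAL33	61	28.6
Nucleus	THI3	61	28.6
Nucleus	DUN1	61	28.6
Nucleus	BPL1	61	28.6
Nucleus	MSH5	61	28.6
Nucleus	GAL3	61	28.6
Nucleus	DAD1	61	28.6
Nucleus	YDR132C	61	28.6
Nucleus	RPA14	61	28.6
Nucleus	SCC2	61	28.6
Nucleus	PRP42	61	28.6
Nucleus	IPK1	61	28.6
Nucleus	GCN4	61	28.6
Nucleus	NUG1	61	28.6
Nucleus	SPC25	61	28.6
Nucleus	HAC1	61	28.6
Nucleus	ACT1	61	28.6
Nucleus	RPL28	61	28.6
Nucleus	RTG	61	28.6
Nucleus	ZPR1	61	28.6
Nucleus	MAL13	61	28.6
Nucleus	SHU1	61	28.6
Nucleus	SRB2	61	28.6
Nucleus	BCY1	61	28.6
Nucleus	MSL1	61	28.6
Nucleus	TAD2	61	28.6
Nucleus	ZAP1	61	28.6
Nucleus	UTP18	61	28.6
Nucleus	PSF2	61	28.6
Nucleus	YJR008W	61	28.6
Nucleus	YJR027W	61	28.6
Nucleus	NMD5	61	28.6
Nucleus	TTI1	61	28.6
Nucleus	RGT1	61	28.6
Nucleus	PHD1	61	28.6
Nucleus	NUP120	61	28.6
Nucleus	MSN4	61	28.6
Nucleus	PMU1	61	28.6
Nucleus	POM34	61	28.6
Nucleus	CHA4	61	28.6
Nucleus	GSP1	61	28.6
Nucleus	GLO1	61	28.6
Nucleus	NSE5	61	28.6
Nucleus	NAT4	61	28.6
Nucleus	CEP3	61	28.6
Nucleus	UBP8	61	28.6
Nucleus	CSL4	61	28.6
Nucleus	SGO1	61	28.6
Nucleus	GSP2	61	28.6
Nucleus	RDR1	61	28.6
Nucleus	CTF19	61	28.6
Nucleus	REC8	61	28.6
Nucleus	YBL005W-A	61	28.6
Nucleus	YGR109W-A	61	28.6
Mitochondrion	TIM12	31	14.6
Mitochondrion	YMC2	31	14.6
Mitochondrion	COS111	31	14.6
Mitochondrion	PGS1	31	14.6
Mitochondrion	CIT2	31	14.6
Mitochondrion	SLM3	31	14.6
Mitochondrion	GDH2	31	14.6
Mitochondrion	PTP1	31	14.6
Mitochondrion	YDR115W	31	14.6
Mitochondrion	RSM24	31	14.6
Mitochondrion	ACN9	31	14.6
Mitochondrion	PAD1	31	14.6
Mitochondrion	AGX1	31	14.6
Mitochondrion	ENO1	31	14.6
Mitochondrion	RRF1	31	14.6
Mitochondrion	ENO2	31	14.6
Mitochondrion	TAO3	31	14.6
Mitochondrion	TES1	31	14.6
Mitochondrion	OPI3	31	14.6
Mitochondrion	TTI1	31	14.6
Mitochondrion	YKL070W	31	14.6
Mitochondrion	GPM1	31	14.6
Mitochondrion	YKT6	31	14.6
Mitochondrion	CBT1	31	14.6
Mitochondrion	ALT1	31	14.6
Mitochondrion	MSS1	31	14.6
Mitochondrion	IRA2	31	14.6
Mitochondrion	CAT5	31	14.6
Mitochondrion	MGE1	31	14.6
Mitochondrion	ALD6	31	14.6
Mitochondrion	GIP3	31	14.6
Ribosome	RPS14A	10	4.7
Ribosome	YDR115W	10	4.7
Ribosome	RSM24	10	4.7
Ribosome	RPL29	10	4.7
Ribosome	RPL28	10	4.7
Ribosome	RPS27B	10	4.7
Ribosome	RPS14B	10	4.7
Ribosome	RPS9A	10	4.7
Ribosome	GIP3	10	4.7
Ribosome	RPL1A	10	4.7
Endoplasmic reticulum	SED4	9	4.2
Endoplasmic reticulum	LCB2	9	4.2
Endoplasmic reticulum	SRP101	9	4.2
Endoplasmic reticulum	DPL1	9	4.2
Endoplasmic reticulum	YDR476C	9	4.2
Endoplasmic reticulum	SEC20	9	4.2
Endoplasmic reticulum	OPI3	9	4.2
Endoplasmic reticulum	ERG5	9	4.2
Endoplasmic reticulum	GIP3	9	4.2
Endomembrane system	SED4	9	4.2
Endomembrane system	COP1	9	4.2
Endomembrane system	LCB2	9	4.2
Endomembrane system	SRP101	9	4.2
Endomembrane system	SEC20	9	4.2
Endomembrane system	APL1	9	4.2
Endomembrane system	NUP120	9	4.2
Endomembrane system	POM34	9	4.2
Endomembrane system	RET3	9	4.2
Plasma membrane	ENO2	3	1.4
Plasma membrane	BCY1	3	1.4
Plasma membrane	APL1	3	1.4
Vacuole	ENO1	3	1.4
Vacuole	ENO2	3	1.4
Vacuole	YKT6	3	1.4
Golgi apparatus	COP1	2	0.9
Golgi apparatus	RET3	2	0.9
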