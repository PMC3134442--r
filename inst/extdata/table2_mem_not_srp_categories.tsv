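category	gene_id	printed_count	printed_percent
Plasma membrane	GPB2	40	7.4
Plasma membrane	APL3	40	7.4
Plasma membrane	FUI1	40	7.4
Plasma membrane	IST2	40	7.4
Plasma membrane	SUL1	40	7.4
Plasma membrane	PHO89	40	7.4
Plasma membrane	GIT1	40	7.4
Plasma membrane	GPR1	40	7.4
Plasma membrane	RGT2	40	7.4
Plasma membrane	SNF3	40	7.4
Plasma membrane	HXT15	40	7.4
Plasma membrane	DNF2	40	7.4
Plasma membrane	HKR1	40	7.4
Plasma membrane	HXT13	40	7.4
Plasma membrane	SHO1	40	7.4
Plasma membrane	RSP5	40	7.4
Plasma membrane	MSB2	40	7.4
Plasma membrane	MTL1	40	7.4
Plasma membrane	MAL11	40	7.4
Plasma membrane	DUR3	40	7.4
Plasma membrane	SLN1	40	7.4
Plasma membrane	PAN1	40	7.4
Plasma membrane	LSB6	40	7.4
Plasma membrane	HXT9	40	7.4
Plasma membrane	STE6	40	7.4
Plasma membrane	TRK2	40	7.4
Plasma membrane	FPS1	40	7.4
Plasma membrane	YPS3	40	7.4
Plasma membrane	PPZ1	40	7.4
Plasma membrane	DFG5	40	7.4
Plasma membrane	PLB3	40	7.4
Plasma membrane	YOL019W	40	7.4
Plasma membrane	SMF1	40	7.4
Plasma membrane	ALR1	40	7.4
Plasma membrane	HXT11	40	7.4
Plasma membrane	SLG1	40	7.4
Plasma membrane	NRT1	40	7.4
Plasma membrane	TRE1	40	7.4
Plasma membrane	OPY2	40	7.4
Plasma membrane	AQY1	40	7.4
Endoplasmic reticulum	CNE1	36	6.7
Endoplasmic reticulum	SWH1	36	6.7
Endoplasmic reticulum	ALG14	36	6.7
Endoplasmic reticulum	SEC66	36	6.7
Endoplasmic reticulum	YPC1	36	6.7
Endoplasmic reticulum	ROT2	36	6.7
Endoplasmic reticulum	YDR056C	36	6.7
Endoplasmic reticulum	YOS9	36	6.7
Endoplasmic reticulum	GTB1	36	6.7
Endoplasmic reticulum	YEL043W	36	6.7
Endoplasmic reticulum	ERJ5	36	6.7
Endoplasmic reticulum	WSC4	36	6.7
Endoplasmic reticulum	EPS1	36	6.7
Endoplasmic reticulum	JEM1	36	6.7
Endoplasmic reticulum	MNS1	36	6.7
Endoplasmic reticulum	LHS1	36	6.7
Endoplasmic reticulum	SRP102	36	6.7
Endoplasmic reticulum	GPT2	36	6.7
Endoplasmic reticulum	MMM1	36	6.7
Endoplasmic reticulum	HRD3	36	6.7
Endoplasmic reticulum	UBX2	36	6.7
Endoplasmic reticulum	MSC1	36	6.7
Endoplasmic reticulum	ERO1	36	6.7
Endoplasmic reticulum	ASI1	36	6.7
Endoplasmic reticulum	SCJ1	36	6.7
Endoplasmic reticulum	LCB1	36	6.7
Endoplasmic reticulum	ASI3	36	6.7
Endoplasmic reticulum	PGA1	36	6.7
Endoplasmic reticulum	LRO1	36	6.7
Endoplasmic reticulum	ARE2	36	6.7
Endoplasmic reticulum	YNR021W	36	6.7
Endoplasmic reticulum	HRD1	36	6.7
Endoplasmic reticulum	MPD2	36	6.7
Endoplasmic reticulum	FLC1	36	6.7
Endoplasmic reticulum	ALG5	36	6.7
Endoplasmic reticulum	YPR091C	36	6.7
Endomembrane system	CNE1	27	5
Endomembrane system	SWH1	27	5
Endomembrane system	APL3	27	5
Endomembrane system	NUP170	27	5
Endomembrane system	ALG14	27	5
Endomembrane system	SEC66	27	5
Endomembrane system	YOS9	27	5
Endomembrane system	NUP157	27	5
Endomembrane system	WSC4	27	5
Endomembrane system	NVJ1	27	5
Endomembrane system	EPS1	27	5
Endomembrane system	MPS3	27	5
Endomembrane system	JEM1	27	5
Endomembrane system	VPS35	27	5
Endomembrane system	SRP102	27	5
Endomembrane system	MMM1	27	5
Endomembrane system	HRD3	27	5
Endomembrane system	UBX2	27	5
Endomembrane system	NUP116	27	5
Endomembrane system	ASI1	27	5
Endomembrane system	LCB1	27	5
Endomembrane system	ASI3	27	5
Endomembrane system	PGA1	27	5
Endomembrane system	HRD1	27	5
Endomembrane system	SEC16	27	5
Endomembrane system	ALG5	27	5
Endomembrane system	APL4	27	5
Golgi apparatus	SWH1	13	2.4
Golgi apparatus	MNN2	13	2.4
Golgi apparatus	SBE2	13	2.4
Golgi apparatus	ANP1	13	2.4
Golgi apparatus	RSP5	13	2.4
Golgi apparatus	EMP47	13	2.4
Golgi apparatus	KEX1	13	2.4
Golgi apparatus	ATG27	13	2.4
Golgi apparatus	MNN5	13	2.4
Golgi apparatus	HOC1	13	2.4
Golgi apparatus	KTR5	13	2.4
Golgi apparatus	GNT1	13	2.4
Golgi apparatus	APL4	13	2.4
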