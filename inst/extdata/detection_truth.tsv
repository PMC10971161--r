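sample_id	cohort_role	diagnosis_gene
S01	patient	SLC2A2
S02	patient	GCDH
S03	patient	CBS
S04	patient	PCCB
S05	patient	PAH
S06	patient	SLC22A5
S07	patient	SLC2A1
S08	patient	PCCA
S09	patient	OAT
S10	patient	ACADM
S11	patient	SLC52A3
S12	patient	FAH
S13	patient	ASS1
S14	patient	BCKDHB
S15	patient	GAMT
S16	patient	ETFB
S17	patient	MMACHC
S18	patient	ACAT1
S19	patient	MMUT
S20	patient	OTC
S21	patient	ACADVL
S22	patient	SLC52A2
S23	patient	MMACHC
S24	patient	DNAJC12
S25	patient	ALDH7A1
S26	patient	IVD
S27	patient	HMGCL
S28	patient	CTNS
S29	patient	G6PC
S30	patient	ETFA
S31	patient	ABCD1
S32	patient	AGL
S33	patient	ASL
S34	patient	BCKDHA
S35	patient	BTD
S36	patient	CAD
S37	patient	CPT2
S38	patient	CYP27A1
S39	patient	FOLR1
S40	patient	GYS2
S41	patient	HADHA
S42	patient	HMGCS2
S43	patient	MCCC1
S44	patient	MCCC2
S45	patient	OXCT1
S46	patient	TH
S47	patient	SLC2A1
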