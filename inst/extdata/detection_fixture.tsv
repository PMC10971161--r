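sample_id	gene	variant_key	hgvs_c	zygosity	status_tNGS	status_WES	status_WGS
S01	SLC2A2	SLC2A2:c.1771-2A>G	c.1771-2A>G	hom	LP_surfaced	LP_surfaced	LP_surfaced
S02	GCDH	GCDH:c.219del	c.219del	het	LP_surfaced	VUS_surfaced	VUS_surfaced
S02	GCDH	GCDH:c.482G>A	c.482G>A	het	LP_surfaced	LP_surfaced	LP_surfaced
S03	CBS	CBS:c.1330G>A	c.1330G>A	het	LP_surfaced	LP_surfaced	not_surfaced
S03	CBS	CBS:c.805_807del	c.805_807del	het	LP_surfaced	LP_surfaced	not_surfaced
S04	PCCB	PCCB:c.1050dup	c.1050dup	het	LP_surfaced	no_data	LP_surfaced
S04	PCCB	PCCB:c.1278_1291delins	c.1278_1291delinsTAGAGCACAGGA	het	LP_surfaced	no_data	LP_surfaced
S05	PAH	PAH:c.1315+1G>A	c.1315+1G>A	het	LP_surfaced	LP_surfaced	LP_surfaced
S05	PAH	PAH:c.261C>A	c.261C>A	het	LP_surfaced	LP_surfaced	LP_surfaced
S06	SLC22A5	SLC22A5:c.-149G>A	c.-149G>A	het	LP_surfaced	not_surfaced	not_surfaced
S06	SLC22A5	SLC22A5:c.610G>A	c.610G>A	het	VUS_surfaced	not_surfaced	not_surfaced
S07	SLC2A1	SLC2A1:c.517-1G>C	c.517-1G>C	het	LP_surfaced	LP_surfaced	LP_surfaced
S08	PCCA	PCCA:c.625G>C	c.625G>C	het	VUS_surfaced	VUS_surfaced	VUS_surfaced
S08	PCCA	PCCA:c.923dup	c.923dup	het	LP_surfaced	LP_surfaced	LP_surfaced
S09	OAT	OAT:c.1058G>A	c.1058G>A	het	LP_surfaced	LP_surfaced	LP_surfaced
S09	OAT	OAT:c.1171del	c.1171del	het	LP_surfaced	LP_surfaced	LP_surfaced
S10	ACADM	ACADM:c.199T>C	c.199T>C	het	LP_surfaced	LP_surfaced	LP_surfaced
S10	ACADM	ACADM:c.985A>G	c.985A>G	het	LP_surfaced	LP_surfaced	LP_surfaced
S11	SLC52A3	SLC52A3:c.639C>G	c.639C>G	het	LP_surfaced	LP_surfaced	LP_surfaced
S11	SLC52A3	SLC52A3:c.678_680del	c.678_680del	het	VUS_surfaced	VUS_surfaced	VUS_surfaced
S12	FAH	FAH:c.674T>G	c.674T>G	het	VUS_surfaced	VUS_surfaced	VUS_surfaced
S12	FAH	FAH:c.1062+5G>A	c.1062+5G>A	het	LP_surfaced	LP_surfaced	LP_surfaced
S13	ASS1	ASS1:c.685_688+4del	c.685_688+4del	het	LP_surfaced	LP_surfaced	LP_surfaced
S13	ASS1	ASS1:c.815G>A	c.815G>A	het	LP_surfaced	LP_surfaced	LP_surfaced
S14	BCKDHB	BCKDHB:c.970C>T	c.970C>T	hom	LP_surfaced	LP_surfaced	LP_surfaced
S15	GAMT	GAMT:c.497T>C	c.497T>C	hom	LP_surfaced	LP_surfaced	LP_surfaced
S16	ETFB	ETFB:c.614_616del	c.614_616delAGA	hom	LP_surfaced	LP_surfaced	LP_surfaced
S17	MMACHC	MMACHC:c.276G>T	c.276G>T	hom	LP_surfaced	LP_surfaced	LP_surfaced
S18	ACAT1	ACAT1:c.662C>T	c.662C>T	het	LP_surfaced	LP_surfaced	LP_surfaced
S18	ACAT1	ACAT1:c.1006-2A>C	c.1006-2A>C	het	LP_surfaced	LP_surfaced	LP_surfaced
S19	MMUT	MMUT:c.454C>T	c.454C>T	het	LP_surfaced	LP_surfaced	LP_surfaced
S19	MMUT	MMUT:c.665A>T	c.665A>T	het	LP_surfaced	LP_surfaced	LP_surfaced
S20	OTC	OTC:c.958C>T	c.958C>T	hom	LP_surfaced	LP_surfaced	no_data
S21	ACADVL	ACADVL:c.104del	c.104del	het	LP_surfaced	LP_surfaced	LP_surfaced
S21	ACADVL	ACADVL:c.848T>C	c.848T>C	het	LP_surfaced	LP_surfaced	LP_surfaced
S22	SLC52A2	SLC52A2:c.148dup	c.148dup	het	LP_surfaced	LP_surfaced	LP_surfaced
S22	SLC52A2	SLC52A2:c.1016T>C	c.1016T>C	het	LP_surfaced	LP_surfaced	LP_surfaced
S23	MMACHC	MMACHC:c.271dup	c.271dup	het	no_data	no_data	LP_surfaced
S23	MMACHC	MMACHC:c.276G>T	c.276G>T	het	no_data	no_data	LP_surfaced
S24	DNAJC12	DNAJC12:c.85del	c.85del	het	LP_surfaced	LP_surfaced	LP_surfaced
S24	DNAJC12	DNAJC12:c.596G>T	c.596G>T	het	LP_surfaced	LP_surfaced	LP_surfaced
S25	ALDH7A1	ALDH7A1:c.1513del	c.1513del	hom	LP_surfaced	LP_surfaced	LP_surfaced
S26	IVD	IVD:c.163A>T	c.163A>T	het	LP_surfaced	LP_surfaced	LP_surfaced
S26	IVD	IVD:c.1169A>G	c.1169A>G	het	VUS_surfaced	VUS_surfaced	VUS_surfaced
S27	HMGCL	HMGCL:c.122G>A	c.122G>A	hom	LP_surfaced	LP_surfaced	LP_surfaced
S28	CTNS	17:3493545-3564028:CNV_del	NA	het	LP_surfaced	LP_surfaced	LP_surfaced
S28	CTNS	CTNS:c.18_21del	c.18_21del	hemi	LP_surfaced	LP_surfaced	LP_surfaced
S29	G6PC	G6PC:c.79del	c.79del	het	LP_surfaced	LP_surfaced	LP_surfaced
S29	G6PC	G6PC:c.788del	c.788del	het	LP_surfaced	LP_surfaced	LP_surfaced
S30	ETFA	ETFA:c.-40G>A	c.-40G>A	hom	not_surfaced	not_surfaced	not_surfaced
S31	ABCD1	ABCD1:c.443A>G	c.443A>G	hemi	LP_surfaced	LP_surfaced	not_surfaced
S32	AGL	AGL:c.16C>T	c.16C>T	het	no_data	LP_surfaced	LP_surfaced
S32	AGL	AGL:c.4529dup	c.4529dup	het	no_data	LP_surfaced	LP_surfaced
S33	ASL	ASL:c.461T>C	c.461T>C	het	LP_surfaced	no_data	LP_surfaced
S33	ASL	ASL:c.532G>A	c.532G>A	het	LP_surfaced	no_data	LP_surfaced
S34	BCKDHA	BCKDHA:c.109-15T>A	c.109-15T>A	hom	not_surfaced	not_surfaced	not_surfaced
S35	BTD	BTD:c.98_104delinsTCC	c.98_104delinsTCC	het	LP_surfaced	LP_surfaced	LP_surfaced
S36	CAD	CAD:c.4595C>T	c.4595C>T	hom	not_surfaced	not_surfaced	not_surfaced
S37	CPT2	CPT2:c.200C>G	c.200C>G	het	LP_surfaced	VUS_surfaced	VUS_surfaced
S37	CPT2	CPT2:c.680C>T	c.680C>T	het	LP_surfaced	LP_surfaced	LP_surfaced
S38	CYP27A1	CYP27A1:c.1016C>T	c.1016C>T	het	LP_surfaced	LP_surfaced	LP_surfaced
S38	CYP27A1	CYP27A1:c.1183C>T	c.1183C>T	het	LP_surfaced	LP_surfaced	LP_surfaced
S39	FOLR1	FOLR1:c.505T>C	c.505T>C	hom	not_surfaced	LP_surfaced	LP_surfaced
S40	GYS2	12:1955262-22837888:CNV_del	NA	het	LP_surfaced	LP_surfaced	LP_surfaced
S40	GYS2	GYS2:c.495+1G>T	c.495+1G>T	het	LP_surfaced	LP_surfaced	LP_surfaced
S41	HADHA	HADHA:c.1528G>C	c.1528G>C	het	LP_surfaced	LP_surfaced	LP_surfaced
S41	HADHA	HADHA:c.2099del	c.2099del	het	LP_surfaced	LP_surfaced	LP_surfaced
S42	HMGCS2	HMGCS2:c.346C>T	c.346C>T	het	VUS_surfaced	not_surfaced	no_data
S42	HMGCS2	HMGCS2:c.634G>A	c.634G>A	het	LP_surfaced	LP_surfaced	no_data
S43	MCCC1	MCCC1:c.639+2T>A	c.639+2T>A	hom	LP_surfaced	LP_surfaced	no_data
S44	MCCC2	MCCC2:c.1367C>T	c.1367C>T	het	LP_surfaced	VUS_surfaced	VUS_surfaced
S44	MCCC2	MCCC2:c.1559A>G	c.1559A>G	het	LP_surfaced	LP_surfaced	LP_surfaced
S45	OXCT1	OXCT1:c.971G>A	c.971G>A	hom	no_data	LP_surfaced	LP_surfaced
S46	TH	TH:c.698G>A	c.698G>A	het	LP_surfaced	LP_surfaced	LP_surfaced
S46	TH	TH:c.1211C>T	c.1211C>T	het	VUS_surfaced	VUS_surfaced	VUS_surfaced
S47	SLC2A1	SLC2A1:c.680-2A>T	c.680-2A>T	het	LP_surfaced	LP_surfaced	LP_surfaced
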