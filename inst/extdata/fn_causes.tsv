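sample_id	method	cause
S06	WES	3'UTR variant filtered out, but present in raw data/other variant VUS
S06	WGS	3'UTR variant filtered out, but present in raw data/other variant VUS
S30	tNGS	hom. VUS/present in raw data
S30	WES	hom. VUS/present in raw data
S30	WGS	hom. VUS/present in raw data
S34	tNGS	hom. VUS/present in raw data
S34	WES	hom. VUS/present in raw data
S34	WGS	hom. VUS/present in raw data
S36	tNGS	hom. VUS/present in raw data
S36	WES	hom. VUS/present in raw data
S36	WGS	hom. VUS/present in raw data
S39	tNGS	hom. VUS/present in raw data
S03	WGS	Low coverage and pseudogene
S31	WGS	Low coverage and pseudogene
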