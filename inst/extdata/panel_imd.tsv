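gene	moi	disorder	chrom
ABCD1	XLR	X-linked adrenoleukodystrophy	X
ACADM	AR	Medium-chain acyl-CoA dehydrogenase deficiency	1
ACADVL	AR	Very-long-chain acyl-CoA dehydrogenase deficiency	17
ACAT1	AR	Beta-ketothiolase deficiency	11
AGL	AR	Glycogen storage disease type III	1
ALDH7A1	AR	Pyridoxine-dependent epilepsy	5
ASL	AR	Argininosuccinic aciduria	7
ASS1	AR	Citrullinemia type I	9
BCKDHA	AR	Maple syrup urine disease type Ia	19
BCKDHB	AR	Maple syrup urine disease type Ib	6
BTD	AR	Biotinidase deficiency	3
CAD	AR	CAD deficiency (early infantile epileptic encephalopathy 50)	2
CBS	AR	Classic homocystinuria	21
CPT1A	AR	Carnitine palmitoyltransferase I deficiency	11
CPT2	AR	Carnitine palmitoyltransferase II deficiency	1
CTNS	AR	Nephropathic cystinosis	17
CYP27A1	AR	Cerebrotendinous xanthomatosis	2
DNAJC12	AR	DNAJC12-deficient hyperphenylalaninemia	10
ETFA	AR	Glutaric acidemia type IIA	15
ETFB	AR	Glutaric acidemia type IIB	19
FAH	AR	Tyrosinemia type I	15
FOLR1	AR	Cerebral folate transport deficiency	11
G6PC	AR	Glycogen storage disease type Ia	17
GAMT	AR	Guanidinoacetate methyltransferase deficiency	19
GCDH	AR	Glutaric acidemia type I	19
GYS2	AR	Glycogen storage disease type 0	12
HADHA	AR	LCHAD deficiency	2
HMGCL	AR	HMG-CoA lyase deficiency	1
HMGCS2	AR	HMG-CoA synthase-2 deficiency	1
IVD	AR	Isovaleric acidemia	15
MCCC1	AR	3-methylcrotonyl-CoA carboxylase 1 deficiency	3
MCCC2	AR	3-methylcrotonyl-CoA carboxylase 2 deficiency	5
MMACHC	AR	Methylmalonic aciduria with homocystinuria, cblC type	1
MMUT	AR	Methylmalonic acidemia, mut type	6
OAT	AR	Gyrate atrophy of choroid and retina	10
OTC	XLR	Ornithine transcarbamylase deficiency	X
OXCT1	AR	Succinyl-CoA:3-oxoacid CoA transferase deficiency	5
PAH	AR	Phenylketonuria	12
PCCA	AR	Propionic acidemia, PCCA type	13
PCCB	AR	Propionic acidemia, PCCB type	3
SLC22A5	AR	Primary carnitine deficiency	5
SLC2A1	AD	GLUT1 deficiency syndrome	1
SLC2A2	AR	Fanconi-Bickel syndrome	3
SLC52A2	AR	Riboflavin transporter deficiency type 2	8
SLC52A3	AR	Riboflavin transporter deficiency type 3	20
TH	AR	Tyrosine hydroxylase-deficient dopa-responsive dystonia	11
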