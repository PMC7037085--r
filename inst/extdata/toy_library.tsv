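iem_id	disease_name	category	gene	omim	incidence	artefact_disclaimer	is_condition	metabolite_name	hmdb_id	mz	direction	fluid	role	only_biomarker	importance	has_endogenous_isomers	isomer_names
PKU	Phenylketonuria	Disorders of nitrogen-containing compounds	PAH	261600	1:10000		no	L-Phenylalanine	HMDB0000159	165.078979	increase	plasma	substrate_or_product	no	critical	no	
PKU	Phenylketonuria	Disorders of nitrogen-containing compounds	PAH	261600	1:10000		no	L-Tyrosine	HMDB0000158	181.073893	decrease	plasma	other	no	supportive	no	
DHPR	Dihydropteridine reductase deficiency	Disorders of nitrogen-containing compounds	QDPR	261630	rare		no	L-Phenylalanine	HMDB0000159	165.078979	increase	plasma	other	no	important	no	
DHPR	Dihydropteridine reductase deficiency	Disorders of nitrogen-containing compounds	QDPR	261630	rare		no	Homovanillic acid	HMDB0000118	182.057909	decrease	plasma	other	no	important	no	
DHPR	Dihydropteridine reductase deficiency	Disorders of nitrogen-containing compounds	QDPR	261630	rare		no	5-Hydroxyindoleacetic acid	HMDB0000763	191.058243	decrease	plasma	other	no	supportive	no	
DNAJC12	DNAJC12 deficiency	Disorders of nitrogen-containing compounds	DNAJC12	617384	rare		no	L-Phenylalanine	HMDB0000159	165.078979	increase	plasma	other	no	important	no	
DNAJC12	DNAJC12 deficiency	Disorders of nitrogen-containing compounds	DNAJC12	617384	rare		no	Homovanillic acid	HMDB0000118	182.057909	decrease	plasma	other	no	supportive	no	
DNAJC12	DNAJC12 deficiency	Disorders of nitrogen-containing compounds	DNAJC12	617384	rare		no	5-Hydroxyindoleacetic acid	HMDB0000763	191.058243	decrease	plasma	other	no	important	no	
GALT	Galactosaemia type I	Disorders of carbohydrates	GALT	230400	1:40000	galactose m/z is shared with glucose and may be masked	no	D-Galactose	HMDB0000143	180.063388	increase	plasma	substrate_or_product	no	critical	yes	D-Glucose
SERDEF	3-Phosphoglycerate dehydrogenase deficiency	Disorders of nitrogen-containing compounds	PHGDH	601815	rare		no	L-Serine	HMDB0000187	105.042593	decrease	plasma	substrate_or_product	no	critical	no	
FASTING	Fasting	Other conditions and interferences					yes	L-Alanine	HMDB0000161	89.047678	decrease	plasma	other	no	supportive	no	
FASTING	Fasting	Other conditions and interferences					yes	L-Glutamine	HMDB0000641	146.069142	decrease	plasma	other	no	supportive	no	
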