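hmdb_id	name	monoisotopic_mass	endogenous
HMDB0000122	D-Glucose	180.063388	yes
HMDB0000143	D-Galactose	180.063388	yes
HMDB0000158	L-Tyrosine	181.073893	yes
HMDB0000159	L-Phenylalanine	165.078979	yes
HMDB0000118	Homovanillic acid	182.057909	yes
HMDB0000763	5-Hydroxyindoleacetic acid	191.058243	yes
HMDB0000187	L-Serine	105.042593	yes
HMDB0000161	L-Alanine	89.047678	yes
HMDB0000641	L-Glutamine	146.069142	yes
HMDB0014322	Valproic acid	144.115030	no
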