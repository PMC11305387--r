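# dockscreen starter SMARTS catalog of assay-interference chemotypes, v1
# format: name<TAB>SMARTS; lines starting with '#' are comments
# This is a compact catalog of well-known interference families; supply a
# full PAINS dialect in the same format to reproduce any published set.
quinone_a	O=C1C=CC(=O)C=C1
catechol_a	[OX2H]c1ccccc1[OX2H]
rhodanine_a	O=C1CSC(=S)N1
azo_a	c[NX2]=[NX2]c
aryl_hydrazone_a	[CX3]=[NX2][NX3]c
aminothiophene_a	[NX3H2]c1cccs1
alkylidene_barbiturate_a	O=C1NC(=O)NC(=O)C1=[CX3]
isothiazolone_a	O=C1C=CSN1
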