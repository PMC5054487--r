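# Tryptophan biosynthesis pathway: chorismate -> L-tryptophan.
# SMILES pin the physiological protonation state of each species (carboxylates
# and phosphates as anions, indole and tryptophan neutral), which is what the
# molecular weights of the reference descriptor table correspond to; no
# automatic (de)protonation is applied downstream.  Indole never diffuses
# freely: it is channeled from the TrpA to the TrpB subunit inside the
# tryptophan synthase complex, so it is flagged and excluded from
# splitting-point prediction.
name	smiles	position	channeled
Chorismate	C(=C)(OC1C=CC(=CC1O)C(=O)[O-])C(=O)[O-]	1	FALSE
Anthranilate	Nc1ccccc1C(=O)[O-]	2	FALSE
N-(5-phosphoribosyl)-anthranilate	[O-]C(=O)c1ccccc1NC1OC(COP(=O)([O-])[O-])C(O)C1O	3	FALSE
1-(o-carboxyphenylamino)-1-deoxyribulose-5-P	[O-]C(=O)c1ccccc1NCC(=O)C(O)C(O)COP(=O)([O-])[O-]	4	FALSE
(1S,2R)-1-C-(indol-3-yl)-glycerol-3-phosphate	c1ccc2c(c1)c(c[nH]2)C(O)C(O)COP(=O)([O-])[O-]	5	FALSE
Indole	c1ccc2c(c1)cc[nH]2	6	TRUE
L-tryptophan	c1ccc2c(c1)c(c[nH]2)C[C@@H](C(=O)O)N	7	FALSE
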