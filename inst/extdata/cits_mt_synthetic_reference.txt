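# Synthetic stand-in for the CitS (PksCT) MT-domain region in CitS numbering.
# The 17 pocket positions and their residues (incl. the His2067/Glu2093
# catalytic dyad) are the published annotation; the carrier sequence is a
# deterministic background draw and may be replaced by the real CitS protein.
name: CitS_MT
offset: 1901
sequence:
RLQSNADTRGCETNFNPLVTRGYSIIFFLNDNFKKNSLDQLFNGFGQQHQSHAVYNQAII
NADCKQEEISINIRGNHHRNMQISEEKGTNLMSKCQKPSYDLMRGNQDRLELMKMLPQDP
GRDMWMEAKRHAAKHNNNWLLTVYARFLDDDADQFDPHIFLQTNLGHASPKHPVFSHQLF
YEPCILLDAEKKEMNLREYWVTQLFAMLLTWYGLLDLDLVADKLIGKIIIDSFLKPPVGG
LQVADDIDENFRQNNDFLNSNGSALCEYLVPPVCRTDGPLQGQYSPTRQTTSAGKKKHQT
pocket:
1938	L	pocket
1942	F	pocket
1954	V	pocket
1955	Y	pocket
1960	I	pocket
1961	N	pocket
2063	T	pocket
2064	N	pocket
2067	H	catalytic_dyad
2093	E	catalytic_dyad
2094	M	pocket
2100	W	pocket
2101	V	pocket
2105	F	pocket
2108	L	pocket
2111	W	pocket
2153	Q	pocket
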