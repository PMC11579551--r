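# Catalog of characterized MT-carrying fungal NR-PKSs.
# Fingerprints are 17-residue readouts at the CitS pocket positions
# 1938,1942,1954,1955,1960,1961,2063,2064,2067,2093,2094,2100,2101,2105,2108,2111,2153.
# Rows other than CitS are PROVISIONAL fixtures: they enforce the documented
# facts (Phe at the 2101 slot in DMOA synthases and DtbA vs Leu in 5-MOA and
# 5-methyl-TAL synthases; nonpolar residues at the 2094 slot in characterized
# synthases; Glu at 2094 in AsbPKS; Leu at 2094 in PksAC) and should be
# refined from curated alignments. methylated_rounds uses '+'-separated
# 1-based elongation-round indices.
name	product	n_extensions	methylated_rounds	fingerprint	group
CitS	citrinin	4	1+2+3	LFVYINTNHEMWVFLWQ	citrinin
AusA	DMOA	3	1+2	LFVYINTNHELWFFLWQ	DMOA
Trt4	DMOA	3	1+2	LFVYINTNHELWFFLWQ	DMOA
AndM	DMOA	3	1+2	LFVYINTNHELWFFLWQ	DMOA
NvfA	DMOA	3	1+2	LFVYINTNHELWFFLWQ	DMOA
DtbA	2,4-dihydroxy-3,5,6-trimethylbenzaldehyde	3	1+2	LFVYVNTNHELWFFLWQ	DMOA
FncE	5-MOA	3	1	LFVYINTNHEMWLFLWQ	5-MOA
mTAL_syn	5-methyl-TAL	2	1	LFVYINTNHEMWLFLWN	5-methyl-TAL
PksAC	unspecified	3	1	LFVYINTNHELWVFLWQ	PksAC
AsbPKS	anhydrosclerotinin B	4	2+3	LFVYINTNHEEWVFLWQ	anhydrosclerotinin
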