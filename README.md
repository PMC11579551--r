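# pksmine

Active-site fingerprinting and genome mining of fungal nonreducing
polyketide synthase (NR-PKS) *C*-methyltransferase (MT) domains.

## What it does and for whom

Fungal NR-PKSs build polyketides iteratively; an embedded MT domain
methylates the growing chain only in the elongation rounds where it
outcompetes the KS domain, and this *methylation program* is hard to
predict from sequence. The crystal structure of the MT domain of the
citrinin synthase CitS (PksCT) defined 17 substrate-binding-pocket
residues — Leu1938, Phe1942, Val1954, Tyr1955, Ile1960, Asn1961, Thr2063,
Asn2064, His2067, Glu2093, Met2094, Trp2100, Val2101, Phe2105, Leu2108,
Trp2111, Gln2153 (His2067/Glu2093 form the catalytic dyad). Reading a
candidate MT domain's residues at these positions, through an alignment to
CitS, gives a 17-character **active-site fingerprint** that correlates with
the methylation program.

`pksmine` is for natural-product genome miners and PKS engineers. It

* locates SAT/KS/AT/PT/ACP/MT domains with position-specific scoring
  profiles and classifies NR-PKS architectures;
* extracts MT domains as *envelope + 30 C-terminal residues*;
* reads out fingerprints: global Needleman–Wunsch alignment to CitS
  (BLOSUM62, affine gaps) and per-pocket-slot residue readout;
* scores novelty against a catalog of characterized synthases — a slot is
  *novel* if its residue is unseen there and a *chemistry change* if its
  class (nonpolar/polar/acidic/basic) is absent there; the score is
  `|novel| + w_class·|chemistry changes|` — and predicts methylation
  patterns by nearest Hamming neighbor;
* builds reference-anchored star MSAs, protein Jukes–Cantor distances
  `d = −(19/20)·ln(1 − 20p/19)`, Neighbor-Joining trees (Newick out),
  Robinson–Foulds tree comparison, and sequence-logo matrices
  `IC = log2(20) − H − 19/(2·ln2·n)`;
* proposes pocket mutations in candidate coordinates (the route from
  "Val2101 of CitS" to an `F2044L`-style variant label);
* computes monoisotopic masses and ESI adduct m/z values
  (`[M+H]+ = M + 1.00727646`);
* generates deterministic synthetic fixtures (multidomain PKS proteins
  with planted domains and prescribed pocket residues) that serve as
  ground truth for the whole chain.

This is the computational procedure by which a PKS carrying an acidic
glutamate at the CitS-2094 slot — nonpolar in every characterized
synthase — was singled out and subsequently characterized as the
anhydrosclerotinin B synthase AsbPKS (a pentaketide synthase methylating
elongation rounds 2 and 3).

## Worked example

```r
library(pksmine)

ref <- cits_reference()
reference_self_fingerprint(ref)
#> [1] "LFVYINTNHEMWVFLWQ"

# a candidate MT domain carrying Glu at the CitS-2094 slot (slot 11)
asb_fp <- reference_self_fingerprint(ref)
substr(asb_fp, 11, 11) <- "E"
cand <- synth_mt_variant(ref, asb_fp, substitution_rate = 0.02, seed = 8)

catalog <- packaged_catalog()
known <- catalog[catalog$name != "AsbPKS", ]   # re-enact the discovery
class(known) <- class(catalog)

fp <- extract_fingerprint(cand$sequence, ref, source_name = "candidate")
novelty_report(fp, known)
#> <novelty_report> candidate  score 3.0  min_distance 1
#>   fingerprint: LFVYINTNHEEWVFLWQ
#>   novel at CitS: 2094
#>   chemistry change at CitS: 2094
#>   nearest: CitS,PksAC (predicted ambiguous)

adduct_mz(parse_formula("C12H12O4"), "[M+H]+")   # anhydrosclerotinin B
#> [1] 221.0808
```

The report says: the candidate's fingerprint differs from the nearest
characterized synthases at exactly one slot, CitS 2094, where its Glu is
both unseen and of a chemistry class (acidic) never observed there — score
3 = 1 novel slot + 2 × 1 chemistry change. Two equidistant neighbors
disagree on the methylation pattern, so the prediction is reported as
ambiguous rather than guessed. The m/z call reproduces the calcd
[M+H]+ value for the C12H12O4 product at four decimals.

The full pipeline (`mine()` / `report_writer()`, or the CLI at
`inst/cli/pksmine.R` with subcommands `mine`, `fingerprint`, `tree`,
`logo`, `mass`, `fixtures`) runs FASTA → architecture → fingerprints →
ranked novelty report with MT/KS trees and per-group logos. See the
methods vignette (`vignettes/mt-fingerprint-mining.Rmd`) for the model,
parameters and design choices.

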