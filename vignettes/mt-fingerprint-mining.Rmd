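---
title: "Active-site fingerprinting and genome mining of NR-PKS MT domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-site fingerprinting and genome mining of NR-PKS MT domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pksmine)
```

## The scientific problem

Fungal nonreducing polyketide synthases (NR-PKSs) are iterative
megasynthases: one SAT–KS–AT–PT–ACP core (plus optional domains) is reused
for every chain-elongation round. When a *C*-methyltransferase (MT) domain
is embedded in the enzyme, it competes with the KS domain for the ACP-bound
β-ketoacyl intermediate, and a methyl group is installed only in the rounds
the MT domain wins. Which rounds those are — the methylation program — is a
property of the enzyme, not of the growing chain, and it is difficult to
predict from sequence alone.

The crystal structure of the MT domain of the citrinin synthase CitS
(PksCT) identified 17 residues lining the substrate-binding pocket
(Leu1938, Phe1942, Val1954, Tyr1955, Ile1960, Asn1961, Thr2063, Asn2064,
His2067, Glu2093, Met2094, Trp2100, Val2101, Phe2105, Leu2108, Trp2111,
Gln2153, with His2067/Glu2093 the catalytic dyad). Reading out the residues
of any other MT domain at these 17 positions — via an alignment to CitS —
gives a 17-character **active-site fingerprint**. Fingerprints of
characterized NR-PKSs correlate with their methylation programs (e.g., the
residue at the CitS-2101 site separates DMOA synthases, which carry Phe,
from 5-MOA synthases, which carry Leu), so a candidate whose fingerprint
contains residues never observed in any characterized synthase — especially
residues of a different chemistry class, such as an acidic glutamate at the
CitS-2094 site where characterized enzymes are uniformly nonpolar — is a
promising target for discovering a new methylation program. That is exactly
the signature by which the anhydrosclerotinin B synthase AsbPKS (a
pentaketide synthase methylating elongation rounds 2 and 3) was singled
out, and this package implements that computational chain as reusable
functions plus a small CLI.

## The procedure

For each candidate protein:

1. **Domain location.** Position-specific scoring matrices (PSSMs) built
   from seed alignments of the six families SAT, KS, AT, PT, ACP, MT are
   aligned locally (affine gaps) against the protein; non-overlapping hits
   above a bit-score threshold become domain envelopes, and the envelope
   order yields the architecture string (NR-PKS flag: KS, AT, PT, ACP all
   present).
2. **MT extraction.** The MT envelope plus 30 additional C-terminal
   residues is extracted — the pocket's final position (CitS 2153) lies
   close to the envelope edge, and the fixed extension protects it from
   envelope trimming.
3. **Fingerprint readout.** The extracted domain is globally aligned to the
   CitS reference (Needleman–Wunsch, BLOSUM62, gap open 10 / extend 1) and
   the candidate residue aligned to each pocket position is read in pocket
   order; a deleted site reads `-`.
4. **Catalog comparison.** Per pocket slot, the candidate residue is tested
   against the multiset of residues observed in a catalog of characterized
   synthases: unseen residues are *novel*, and novel residues whose
   chemistry class (nonpolar / polar / acidic / basic) is absent from the
   slot are *chemistry changes*. The novelty score is
   `|novel| + w_class * |chemistry changes|`; the methylation pattern of
   the minimum-Hamming-distance catalog entry is transferred as the
   prediction (ties with conflicting patterns are reported as ambiguous).
5. **Phylogeny and logos.** Extracted MT domains are merged into a
   reference-anchored star MSA; pairwise mismatch proportions over mutually
   non-gap columns are corrected with the 20-state protein Jukes–Cantor
   formula `d = -(19/20) ln(1 - 20p/19)` and fed to Neighbor-Joining.
   Optionally a KS-domain tree is built the same way and compared with the
   MT tree by Robinson–Foulds distance (the two families show similar
   groupings, consistent with co-evolution). Per-group sequence logos
   report column frequencies and information content
   `IC = log2(20) - H - e_n`, `e_n = 19 / (2 ln2 n)`.
6. **Mutation design.** A CitS-numbered pocket site is mapped through the
   alignment into candidate coordinates and rendered as a standard mutation
   label — the route from "Val2101 of CitS" to the F2044L variant of NvfA,
   or from "Met2094 of CitS" to the E2052M/E2052L variants of AsbPKS.

## A worked mining run

```{r mining}
ref <- cits_reference()
reference_self_fingerprint(ref)

# a candidate carrying Glu at the CitS-2094 slot (slot 11), like AsbPKS
asb_fp <- reference_self_fingerprint(ref)
substr(asb_fp, 11, 11) <- "E"
cand <- synth_mt_variant(ref, asb_fp, substitution_rate = 0.02, seed = 8)

catalog <- packaged_catalog()
known <- catalog[catalog$name != "AsbPKS", ]  # re-enact the discovery
class(known) <- class(catalog)

fp <- extract_fingerprint(cand$sequence, ref, source_name = "candidate")
novelty_report(fp, known)
```

The report flags CitS 2094 as both novel and chemistry-changing and assigns
score 3 (one chemistry change at the default `w_class = 2`). Two catalog
entries (CitS and PksAC) tie at Hamming distance 1 but disagree on their
methylation pattern, so the prediction is honestly reported as ambiguous —
appropriately, since a chemistry-changing candidate is exactly the case
where nearest-neighbor transfer should not be trusted. The HRMS side of the
story is one call:

```{r mass}
adduct_mz(parse_formula("C12H12O4"), "[M+H]+")  # anhydrosclerotinin B
```

## Parameters that matter

* **`scan_threshold` (bits, default 40).** Minimum local-alignment score of
  a reported domain hit. Calibrated on the packaged profiles: the best
  background-only alignment over 1.5 kaa of random sequence scores 17–26
  bits, while genuine domain hits score above 200 bits even at 10% point
  substitution, so 40 bits sits an order of magnitude from both regimes.
  Profiles built from other seeds may need a different threshold.
* **`pseudocount_weight` (default 0.5).** Shrinkage of PSSM column
  frequencies toward the background; 0 scores raw frequencies (unobserved
  residues floored at −20 bits), large values flatten the profile.
* **Gap penalties.** Profile scan: open 8 / extend 1 bits. Global
  alignment to the reference: open 10 / extend 1 against BLOSUM62, a
  standard pairing; both configurable.
* **`w_class` (default 2).** Weight of chemistry-class changes in the
  novelty score. The default makes one cross-class residue outrank two
  merely-unseen same-class residues, reflecting that the discovery signal
  was a polarity change, not just an unusual residue.
* **`nj_cap` (default 10).** Distance assigned to saturated pairs
  (`p >= 19/20`) where the Jukes–Cantor logarithm diverges.
* **Logo correction.** The small-sample term `e_n` uses the per-column
  non-gap count; it is on by default and clamped so IC stays in
  `[0, log2 20]`.

## The synthetic-fixture generator

All ground-truth testing uses generated data: i.i.d. background sequence
from a fixed average amino-acid composition, MT variants that plant a
prescribed 17-residue fingerprint into the reference scaffold and then
substitute non-pocket sites at a chosen rate, multidomain proteins that
concatenate per-family ancestor blocks with 20–60-residue background
linkers, and catalogs whose group fingerprints are perturbed *within
chemistry class* (conservative substitutions, so group chemistry profiles
stay stable while exact residues vary). Every generator is a pure function
of its parameters and seed.

What this emulates — and what it does not: planted domains are
substitution-diverged copies of single ancestors, so the fixtures exercise
envelope detection, coordinate mapping and fingerprint readout, but they do
not contain indel-diverged domains, shuffled architectures, splice-variant
artifacts, or the deep homology structure of real NR-PKS families. Passing
the fixture suite therefore demonstrates that the chain is implemented
correctly, not that the packaged fixture profiles would detect remote
homologs in real proteomes; for production mining, curated seed alignments
should replace the packaged synthetic seeds.

## Numerical and design choices

* **Coordinates** are 1-based inclusive throughout, matching CitS residue
  numbering.
* **The packaged reference sequence is a synthetic stand-in**: the 17
  pocket annotations (positions, residues, dyad) are the published ones,
  but the carrier sequence is a deterministic background draw spanning CitS
  1901–2200. Correctness of every readout is defined against the
  annotation, so users can substitute the real CitS protein via
  `read_reference()` without touching code.
* **Catalog rows are partly provisional.** Only some residue facts are
  stated as text (F vs L at the 2101 slot; nonpolar at 2094; AsbPKS's Glu);
  full per-synthase fingerprints ship as editable best-effort fixtures.
  Methylation patterns encode the documented facts (5-MOA and 5-methyl-TAL
  methylate only round 1; AsbPKS methylates rounds 2 and 3 of its 4
  elongations — a pentaketide from an acetyl starter takes 4 extensions);
  DMOA rows use the provisional convention of rounds {1,2} over 3
  extensions.
* **Profiles are PSSMs, not profile HMMs.** Seed columns with more than
  50% gaps are dropped as insert states; the remaining columns score
  `log2((f + alpha q) / ((1 + alpha) q))`. This is self-contained and
  adequate for envelope finding on fixture-scale problems; an HMM backend
  could be swapped in behind the same hit interface.
* **Alignment and tree building are delegated** to Biostrings
  (Needleman–Wunsch) and ape (Neighbor-Joining), with deterministic
  behavior; negative NJ branch lengths are clamped to zero. The star MSA
  left-justifies member insertions in shared insertion blocks.
* **Jukes–Cantor for proteins** uses the 20-state factor 19/20. Gap
  handling: mismatch proportions count only mutually non-gap columns.
* **Protonation uses the proton mass** (1.00727646 Da), not the H-atom
  mass — the electrospray convention that reproduces the printed
  [M+H]+ value for C12H12O4 at four decimals.
* **Ties.** Nearest-neighbor pattern prediction reports conflicts as
  `ambiguous` rather than guessing; candidate ranking breaks score ties by
  larger minimum distance (more isolated first), then name.

## Problem sizes used in the shipped checks

The packaged test-and-verification runs use fixture-scale problems chosen
to exercise every code path while keeping a full run fast on a laptop:
6-domain proteins of roughly 1.3 kaa, 20 scan-recovery replicates at 10%
substitution, 40 full-pipeline replicates at 5%, 20 random additive trees
of up to 8 leaves for the Neighbor-Joining property, and a 4-group x 3-member
synthetic catalog for the mining re-enactment.

## Known limitations

* Only the six NR-PKS families are modeled; reducing domains (KR/DH/ER),
  thioesterases and trans-acting partners are out of scope, so the NR-PKS
  flag means "core NR architecture present", not "no reducing domain
  anywhere".
* The fingerprint is alignment-based; no structural superposition is
  attempted, so readouts degrade for MT domains too diverged for a reliable
  global alignment to CitS.
* The novelty score is a formalization of a judgement the original
  screening made by eye; its defaults are documented, not canonical.
* Nearest-neighbor pattern transfer cannot predict genuinely new programs —
  by construction it labels them via their closest characterized relative,
  which is precisely why the novelty flags, not the predicted pattern, are
  the mining signal.
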