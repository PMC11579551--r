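Package: pksmine
Title: Active-Site Fingerprinting and Genome Mining of Fungal
    Nonreducing Polyketide Synthase Methyltransferase Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Locates SAT, KS, AT, PT, ACP and C-methyltransferase (MT)
    domains in fungal nonreducing polyketide synthase (NR-PKS) proteins
    with position-specific scoring profiles, extracts MT domains with the
    30-residue C-terminal extension rule, reads out the 17 substrate-
    binding-pocket residues of the citrinin synthase (CitS) MT domain as
    an active-site fingerprint, compares candidates against a catalog of
    characterized synthases (Jukes-Cantor/Neighbor-Joining phylogenies,
    sequence logos, novelty scoring with chemistry-class changes),
    predicts methylation patterns by nearest neighbor, proposes active-
    site point mutations in candidate coordinates, and computes
    monoisotopic masses and electrospray adduct m/z values for product
    formulas. Ships a synthetic-fixture generator for multidomain PKS
    proteins with planted domains and prescribed pocket residues.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    ape,
    jsonlite,
    phangorn,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
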