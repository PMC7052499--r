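Package: walnutid
Title: Karyotype, Early-Fruiting-Gene Phylogenetics and SSR Identification
    Keys for Sichuan Walnut Cultivars
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable, tested implementations of the three molecular
    procedures used to distinguish Sichuan walnut (Juglans) cultivars:
    numeric karyotype analysis (length-ordered chromosome numbering and
    the longest/shortest chromosome ratio over metaphases), maximum
    likelihood phylogenetics of an early-fruiting gene fragment under the
    Tamura-Nei (TN93) substitution model (complete-deletion filtering,
    closed-form pairwise distances, neighbor-joining and BioNJ starting
    trees, Felsenstein pruning likelihood with branch-length optimization
    and nearest-neighbor-interchange search, two-group monophyly check),
    and construction of SSR microsatellite identification keys (peak
    height filtering, cultivar-exclusive alleles, anchor-plus-exclusion
    combination keys, greedy minimal discriminating allele sets) together
    with seeded simulators for genotype tables and sequence alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
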