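Package: mtfootprint
Title: Detecting Incipient Population Subdivision from Mitochondrial
    Phylogenetic Footprints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects incipient population subdivision from mitochondrial
    haplotype alignments in situations where conventional F-statistics are
    near zero. Implements per-site base-composition heterogeneity tests
    between two populations (Fisher exact tests with codon-position and
    synonymy annotation), Tamura-Nei (1993) distances with invariant-sites
    and gamma-rate corrections, neighbor-joining tree construction, Fitch
    parsimony with accelerated-transformation (ACCTRAN) character mapping to
    locate convergent "footprint" clades, and an AMOVA-based phi-ST
    permutation test. Includes a two-deme structured-coalescent simulator of
    concatenated mitochondrial genes for power and calibration studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
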