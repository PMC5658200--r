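Package: rrnhet
Title: Detection and Characterization of Divergent Ribosomal Operon Types
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and characterizing intragenomic
    macroheterogeneity among ribosomal RNA (rrn) operons in prokaryotes,
    motivated by cyanobacterial strains that carry one highly divergent
    operon alongside several near-identical copies. Provides operon typing
    from consistently variable alignment positions, p-distance and percent
    identity with pairwise deletion, 16S-23S internal transcribed spacer
    (ITS) domain annotation, helix-level secondary-structure comparison
    under canonical base pairing with a mismatch-closure rule, sigma-70
    promoter consensus scoring, genospecies delimitation from identity,
    phylogeny and morphology criteria, type-specific primer window design,
    and a seeded synthetic-data generator emulating multi-operon strains
    and clone libraries for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
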