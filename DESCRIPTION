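Package: snptracer
Title: Strain Traceability via Private SNPs and Allele-Specific PCR
Version: 0.1.0
Authors@R:
    person("snptracer", "developers", email = "snptracer@example.org",
           role = c("aut", "cre"))
Description: Tools to trace microbial strains (typically oenological
    Saccharomyces cerevisiae) through strain-private single-nucleotide
    polymorphisms. Discovers private SNP markers from multi-sample variant
    calls, designs allele-specific (ARMS) PCR assays with an engineered
    -2 destabilizing mismatch and amplicon-size separation rules, assembles
    multiplex panels with a touch-down thermal protocol, and verifies designs
    by simulated allele-specific PCR and inter-delta fingerprinting, gel
    band-pattern strain assignment, and unshared-variant neighbor-joining
    phylogeny. A seeded synthetic-data generator emulates a clustered strain
    collection so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
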