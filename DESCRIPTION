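Package: vqsurvey
Title: Genome-Wide VQ Gene-Family Survey Tools for Polyploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for genome-wide surveys of the VQ
    transcriptional-cofactor gene family in polyploid (notably hexaploid)
    plant genomes. Provides deterministic VQ-motif (FxxhVQxhTG) scanning and
    variant typing, protein physicochemical descriptors (molecular weight,
    isoelectric point, instability index, aliphatic index, GRAVY),
    gene-structure and chromosome-distribution summaries, homoeolog-triad
    ratio classification across A/B/D subgenomes, duplication-pair detection
    with Nei-Gojobori (1986) Ka/Ks estimation and selection calls,
    MISA-equivalent microsatellite (SSR) mining with compound-repeat merging,
    promoter cis-regulatory element scanning against an IUPAC consensus
    catalog (W-box and PlantCARE-style defaults), neighbor-joining phylogeny
    with bootstrap support and reference-guided subgroup assignment, and
    RNA-seq TPM / qRT-PCR (2^-ddCt) expression summaries. A seeded synthetic
    hexaploid genome generator with a ground-truth manifest supports
    end-to-end validation without any external genome download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
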