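Package: dccrex
Title: Hierarchical Analysis of Dosage Compensation Complex Recruitment Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify and characterize hierarchical recruitment
    sites of the C. elegans dosage compensation complex (DCC) from ChIP
    coverage data. Implements median normalization and input subtraction of
    coverage tracks, replicate-consensus and summit-split peak sets,
    two-component Gaussian mixture detection of recruitment foci, 400-bp
    recruitment-site definition by multi-protein overlap with H3K4me3
    exclusion, k-means strength classification, biophysical position weight
    matrix affinity scanning standardized to a 0-10 scale, homotypic motif
    cluster detection, sliding-window quantification of domain-scale binding
    loss after recruitment-site deletions, TAD-boundary proximity and
    region-overlap permutation tests, windowed Fisher tests of expression
    response, delta-delta-Ct ChIP-qPCR quantification, and contact-matrix
    interaction counting. A synthetic-data module generates genomes, ChIP
    experiments, deletion strains, and ancillary data with the statistical
    structure the analysis assumes, so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
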