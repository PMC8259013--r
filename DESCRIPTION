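Package: meripArray
Title: Analysis of m6A Epitranscriptomic Two-Color Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantification and differential analysis of N6-methyladenosine
    (m6A) epitranscriptomic microarrays in which the immunoprecipitated
    (Cy5) and supernatant (Cy3) fractions of each sample are hybridized as
    two channels. Implements spike-in control normalization, per-transcript
    percent-modification and expression quantification, fold-change plus
    Student's t differential methylation/expression calling, four-quadrant
    methylation-by-expression integration with cross-comparison concordance,
    Fisher's exact gene-set over-representation with -log10(P) enrichment
    scores, lncRNA genomic-context classification and 300-kb cis-gene
    linkage, and MeRIP-qPCR / 2^-ddCt validation arithmetic. A seeded
    synthetic-data generator with planted effects makes every stage testable
    without access to raw arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    fgsea,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
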