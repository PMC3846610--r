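Package: PatternGenes
Title: Quantitative Identification of Pattern Genes from Expression Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies pattern genes (specific, selective, housekeeping and
    repressed) from nonnegative gene-by-sample expression matrices using four
    cosine-geometry statistics: the specificity measure (SPM), the dispersion
    measure (DPM), the contribution measure (CTM) and the repression measure
    (RPM), together with the conventional fractional-expression baseline
    (r/SUM). Includes microarray-style preprocessing (detection-call zeroing,
    replicate averaging, probeset collapse by maximal standard deviation),
    readers for delimited expression tables and GEO SOFT GDS full tables, a
    planted-signal synthetic data generator with truth labels, report writers,
    and a command-line interface over the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
biocViews: GeneExpression, Microarray, Classification, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
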