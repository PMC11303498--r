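Package: updscreen
Title: Batch Detection of Uniparental Disomy from Exome Variant Calls
Version: 0.1.0
Authors@R: person("UPD", "Screen Maintainers", email = "updscreen@example.org",
    role = c("aut", "cre"))
Description: Screens single, duo and trio exome (or genome) variant calls for
    uniparental disomy. Computes per-chromosome runs-of-homozygosity (ROH)
    fractions and parental inheritance ratios (IR), tags chromosomes with
    published cutoffs (ROH low < 0.2, mixed 0.2-0.7, high > 0.7; IR > 2 in
    duos, > 5 in trios) to call isodisomy, heterodisomy and segmental UPD
    candidates, flags suspected consanguinity, and emits batch-filterable
    cohort tables plus diagnostic allele-fraction and cohort scatter plots.
    Includes a synthetic trio-cohort simulator with ground-truth UPD events
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    stats,
    utils,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    S4Vectors
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
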