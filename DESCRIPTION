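Package: cnvrecur
Title: Recurrent Copy-Number-Variant Regions and Candidate Gene Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies genomic regions recurrently deleted or duplicated
    across a patient cohort, tests whether the observed overlap exceeds a
    genome-shuffling null with an empirical permutation p-value, prioritizes
    candidate genes by recurrence, regional gene count and embryonic palate
    expression, quantifies enrichment of a curated disease-gene panel by the
    hypergeometric test, scores the population structural-variant density of
    candidate loci in fixed genomic windows, and maps patient phenotype terms
    to top-level ontology categories. Ships a synthetic-data generator that
    emulates every input with planted ground truth so the full pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
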