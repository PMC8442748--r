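Package: bsascan
Title: Bulked-Segregant Mapping of a Recessive Locus from Pooled
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bulked-segregant analysis (BSA-seq) of an F2 population
    segregating a monogenic recessive trait. Provides a synthetic F2
    bulk-sequencing simulator (Haldane meiosis, Poisson pool depths),
    the four-rule variant filter applied to pooled SNP calls,
    SNP-index / delta-SNP-index and Euclidean-distance association
    scans with sliding-window fitting, theoretical, percentile and
    median+3SD thresholds, candidate-region extraction, Mendelian
    segregation tests, and codon-level variant-effect classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    stats,
    tibble,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
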