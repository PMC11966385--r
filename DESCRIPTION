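Package: hybriseek
Title: Genomic Parentage Inference for Clonal Hybrid Cultivars
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the parentage of clonally propagated hybrid crop
    cultivars from multi-sample SNP data. Implements diagnostic-SNP genome
    painting against two reference species panels, method-of-moments
    identity-by-descent estimation, a deterministic haplotype-copying
    analysis yielding per-donor shared-fragment counts, a trio Mendelian
    compatibility ("coincidence probability") statistic with exhaustive
    candidate-parent-pair ranking, and chloroplast-distance seed-parent
    assignment. Ships a pedigree-aware synthetic SNP data generator with
    machine-readable ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
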