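Package: homeobias
Title: Expression Level Dominance and Homeolog Expression Bias in Hybrid
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing homeolog-specific expression in F1 hybrids
    and allopolyploids from transcript-level read counts: reciprocal
    best-hit homeolog pairing from tabular alignment hits, TPM and RPKM
    normalisation with expression filtering and Spearman sample QC,
    classification of hybrid expression patterns (additivity, parental
    expression level dominance, transgressive expression) by replicate-level
    t-tests, homeolog expression bias (HEB) statistics with binomial
    likelihood-ratio tests and Benjamini-Hochberg FDR control,
    between-condition bias-change (delta-HEB) homogeneity tests, and a
    negative-binomial count simulator with planted ground truth for
    validating every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
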