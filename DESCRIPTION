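Package: fbatrare
Title: Family-Based Rare-Variant Association Tests with Collapsing and
    Window Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Family-based association tests for rare variants in extended
    pedigrees. Rare variants (founder minor allele frequency below a
    threshold) are collapsed into a single weighted pseudo-marker, either
    unweighted (v0) or with Madsen-Browning inverse square-root frequency
    weights (v1), and tested with a quantitative-trait FBAT score statistic
    that conditions offspring genotypes on parental genotypes within
    nuclear families. Includes a disjoint 100-kb window scan with
    Bonferroni correction, a gene-dropping pedigree simulator producing
    GAW18-like data sets with known causal variants, and a multi-replicate
    power and type-I-error evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
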