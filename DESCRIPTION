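Package: mirstab
Title: Selection of Stably Expressed Reference miRNAs from NanoString
    nCounter Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for choosing candidate reference (normalizer) miRNAs
    from NanoString nCounter molecule-count data. Implements low-count
    probe filtering, four log2 normalization strategies (housekeeping
    mRNAs, total miRNA content, the 75 most represented miRNAs, and the
    positive spike-in controls), four variability measures with rank-sum
    aggregation into a combined stability ranking, paired Grambsch and
    Bonett-Seier dispersion tests on composite normalizers, and a
    permutation test on rank concordance for comparing normalization
    strategies with Benjamini-Hochberg adjustment. A negative-binomial
    simulator produces nCounter-like count matrices with planted stable
    and group-differential miRNAs so the whole pipeline can be exercised
    and calibrated on data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
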