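Package: hynet
Title: Hypernetwork Analysis of Transcriptome Co-Expression Organisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how coordinated the transcriptome-wide co-expression
    of a differentially expressed (DE) gene set is. Counts are normalised with
    median-of-ratios size factors, filtered, and contrasted against a control
    condition to select DE genes; Manhattan distances between each DE gene and
    all other transcripts are binarised at a centile threshold into an
    incidence matrix M, whose product M t(M) is a hypernetwork of
    shared-relationship counts. Mean connectivity and per-gene Shannon entropy
    summarise the hypernetwork, and a randomised gene-set null with empirical
    p-values tests whether the observed set is more connected and more
    organised than chance. A negative-binomial simulator with a tunable
    coordinated co-expression module generates matched synthetic data for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    limma,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
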