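Package: nacbs
Title: Palindromic NAC Binding Site Models and Senescence Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying transcriptional regulation during cereal flag
    leaf senescence. Builds palindromic NAC binding site (NACBS) letter
    probability models with variable inverted-repeat spacers, scans promoter
    sequences FIMO-style with exact p-values from a dynamic program over a
    discretized log-odds score grid, and tests hypergeometric
    over-representation of NACBS-containing promoters in differentially
    expressed gene sets. Supporting stages cover single-channel microarray
    preprocessing (background correction, quantile normalization, low-signal
    filtering, 3'-biased probe deduplication, moderated differential ranking),
    qPCR Ct processing with geNorm reference-gene stability and k-means
    clustering of senescence profiles ordered by chlorophyll content, and
    co-expression rank-bias analysis. A synthetic-data module generates
    promoters with planted motifs, redundant-probe microarrays, archetype
    expression panels and Ct tables with ground truth, so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    limma,
    stats,
    tools,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
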