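Package: trinorm
Title: Three-Viewpoint Normalization of Repeated-Measures RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models bulk RNA-seq transcript counts from repeated-measures designs
    under three normalization viewpoints: per-library-size (trimmed mean of
    M-values scaled library sizes), per-total-RNA (fixed RNA input), and
    per-sample-size (tissue mass). Implements stable-reference-gene selection by
    a linear mixed-model t-value screen followed by intraclass-correlation
    ranking, stable-gene-derived sample references, negative binomial
    generalized linear mixed models with participant random intercepts and
    normalization offsets, Benjamini-Hochberg false discovery rate control, and
    cross-mode comparison of differential expression calls. Includes a
    synthetic-data generator emulating global transcriptome amplification in a
    bilateral resistance-training study so the whole analysis runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    lme4,
    edgeR,
    glmmTMB,
    MASS,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
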