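Package: looparray
Title: Mixed-Model Analysis of Two-Color Loop-Design Expression Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of two-color (Cy3/Cy5) loop-design
    expression microarrays: pilot-array probe selection by intensity-ratio
    ranking, spot-level intensity and presence filtering, log2 transformation,
    global mixed-model normalization (dye and block fixed effects; array,
    array-by-dye and array-by-block random effects), per-transcript mixed
    ANOVA on normalization residuals with Satterthwaite degrees of freedom
    and Benjamini-Hochberg false discovery rate control, and downstream set
    and multivariate statistics (PCA variance partitioning, Ward and k-means
    clustering, Venn accounting, hypergeometric overlap with representation
    factors, term enrichment with ancestor-slim mapping, two-count proportion
    tests, and qPCR relative-expression statistics). Includes a synthetic
    loop-design experiment generator with known ground truth so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    emmeans,
    pbkrtest,
    withr
Config/testthat/edition: 3
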