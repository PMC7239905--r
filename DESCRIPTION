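Package: panomix
Title: Pan-Cancer Multi-Omic Integration by Sparse Singular Value Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Integrates multiple omic blocks (gene expression, DNA methylation,
    copy number) measured on the same samples into a single extended matrix,
    removes tissue-of-origin effects by linear projection onto the orthogonal
    complement of a membership design, extracts sparse axes of variation with
    an elastic-net penalized singular value decomposition fitted by alternating
    thresholded power iterations with deflation, discovers sample clusters with
    cost-selected t-SNE followed by silhouette-tuned density clustering, and
    characterizes clusters through gene scores, ANOVA/Tukey signature calling,
    Kruskal-Wallis/Dunn phenotype association, log-rank survival comparison and
    hypergeometric over-representation of gene sets. Includes a synthetic
    multi-omic data generator with known ground truth for calibration and
    testing, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    Rtsne,
    cluster,
    survival,
    mclust,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
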