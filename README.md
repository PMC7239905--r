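# panomix

Pan-cancer multi-omic integration by sparse singular value decomposition,
for researchers asking whether tumors group by shared molecular alterations
once the dominant tissue-of-origin signal is removed.

A cohort profiled on several omic platforms — gene expression (GE), DNA
methylation (METH), copy number (CNV) — is integrated as a single extended
matrix of standardized, block-weighted features,

    X = [X1, ..., XL],      each column of block l scaled so the block
                            carries total energy n (division by sqrt(p_l)),

tissue effects are projected out with the annihilator of the one-hot
membership design Q,

    X_perp = (I - Q (Q'Q)^-1 Q') X,

and sparse axes of variation are extracted one rank-1 layer at a time by
minimizing

    || X - d z w' ||_F^2  +  lambda ( alpha ||w||_1 + (1 - alpha) ||w||_2^2 ),

with alternating thresholded power iterations and deflation. The penalty is
tuned per axis at the sharpest bend of the proportion-of-variance-explained
(PVX) curve; the rank comes from the scree bend of the pre-projection
spectrum. The retained score axes are mapped to two dimensions with
cost-selected t-SNE, clusters are found with silhouette-tuned DBSCAN, and
each cluster is characterized through per-gene scores (a gene's selected
features weighted by their loadings): ANOVA with Bonferroni control, Tukey
pairwise tests, and an exclusivity rule that defines a cluster's signature
as the genes deregulated in that cluster versus every other one. Phenotypes
are tested with Kruskal-Wallis/Dunn, survival with the log-rank test, gene
sets with a hypergeometric over-representation test.

A synthetic multi-omic generator with full ground truth (tissue labels,
cluster labels, factor scores/loadings with known support, signature genes,
missing-data masks) drives calibration and testing.

## A worked example

```r
library(panomix)

dir <- tempfile("panomix")
fx  <- make_fixture(dir, preset = "tiny", seed = 42)   # 120 samples,
# 3 omic blocks (200/300/150 features), 3 tissues, 4 planted classes
manifest <- run_pipeline(fx$config, truth = fx$truth)

manifest$n_axes
#> [1] 5
manifest$clustering$n_clusters
#> [1] 4
manifest$recovery$ari_clusters
#> [1] 1
manifest$recovery$ari_tissues
#> [1] 0.018
```

The pipeline keeps 5 axes (the bend of the raw scree), finds the 4 planted
classes exactly (adjusted Rand index 1 against the planted clusters, ~0
against tissues — tissue structure is gone). Running the identical
configuration with the projection stage disabled flips the outcome:

```r
fx$config$stages$project <- FALSE
fx$config$out_dir <- file.path(dir, "results_raw")
manifest_raw <- run_pipeline(fx$config, truth = fx$truth)
manifest_raw$recovery$ari_tissues
#> [1] 0.887
```

without tissue removal the same machinery recovers the tissue partition
instead — the central behavior the package exists to demonstrate. Every
stage writes TSV artifacts plus a JSON manifest (parameters, seed,
checksums) under the configured output directory, and reruns are
bit-identical.

Fitted objects follow broom conventions — `tidy()`, `glance()`,
`autoplot()`:

```r
fit <- fit_ssvd(X, n_axes = 5)      # X an extended_matrix
tidy(fit)                           # axis / feature_id / loading (nonzero)
glance(fit)                         # axes, selected features, PVX
autoplot(embedding, clusters = cl)  # t-SNE map colored by cluster
```

A thin command-line front end ships in `inst/cli/panomix.R`:

```sh
Rscript inst/cli/panomix.R fixture --out-dir demo --preset tiny --seed 42
Rscript inst/cli/panomix.R run --config demo/config.yaml
Rscript inst/cli/panomix.R run --config demo/config.yaml --no-project \
    --out-dir demo/results_raw
```

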