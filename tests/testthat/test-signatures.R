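ssvd_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- generate_multiomic(funnel_benchmark_config())
      X <- standardized_extended(g)
      fit <- fit_ssvd(X, n_axes = 3)
      cache <<- list(g = g, X = X, fit = fit)
    }
    cache
  }
})

test_that("gene scores equal the explicit dense product", {
  fx <- ssvd_fixture()
  gst <- gene_scores(fx$X, fx$fit)
  expect_gt(ncol(gst$scores), 0)
  # dense oracle: rebuild each gene's score by explicit multiplication
  W <- fx$fit$W[fx$fit$selected_axes, , drop = FALSE]
  w_comb <- as.vector(crossprod(W, fx$fit$d[fx$fit$selected_axes]))
  names(w_comb) <- colnames(fx$fit$W)
  for (gene in utils::head(gst$gene_ids, 10)) {
    feats <- gst$contributing_features[[gene]]
    oracle <- as.vector(fx$X$values[, feats, drop = FALSE] %*% w_comb[feats])
    expect_lt(max(abs(gst$scores[, gene] - oracle)), 1e-10)
  }
  # every scored gene has at least one selected feature; genes with no
  # selected feature are absent, not zero-filled
  sel_genes <- unique(fx$X$features$gene_id[fx$fit$feature_support])
  expect_true(all(gst$gene_ids %in% sel_genes))
  absent <- setdiff(fx$X$features$gene_id, sel_genes)
  expect_false(any(absent %in% gst$gene_ids))
})

test_that("a single selected unit-loading feature passes through as the score", {
  v <- matrix(rnorm(40), 20, 2,
              dimnames = list(sprintf("S%02d", 1:20), c("gA_GE", "gB_GE")))
  X <- concatenate_blocks(list(omic_block(v, kind = "GE")))
  fit <- structure(list(
    Z = matrix(0, 20, 1), W = matrix(c(1, 0), 1, 2,
                                     dimnames = list(NULL, colnames(v))),
    d = 1, lambdas = 0.1, alpha = 0.5, pvx_path = list(),
    selected_axes = 1L, feature_support = c(TRUE, FALSE), pvx = NA,
    converged = TRUE
  ), class = "ssvd")
  gst <- gene_scores(X, fit)
  expect_identical(gst$gene_ids, "gA_GE")
  expect_equal(unname(gst$scores[, 1]), unname(v[, 1]))
})

test_that("functional-class scores aggregate member genes' features", {
  fx <- ssvd_fixture()
  sets <- list(setA = utils::head(fx$g$truth$signature_genes$gene_id, 12))
  gst <- gene_scores(fx$X, fx$fit, gene_sets = sets)
  present <- intersect(sets$setA, gst$gene_ids)
  expect_gt(length(present), 0)
  expect_identical(colnames(gst$class_scores), "setA")
  oracle <- rowSums(gst$scores[, present, drop = FALSE])
  expect_lt(max(abs(gst$class_scores[, 1] - oracle)), 1e-10)
})

test_that("ANOVA flags planted shifts and respects the Bonferroni family", {
  fx <- ssvd_fixture()
  gst <- gene_scores(fx$X, fx$fit)
  cl <- fx$g$truth$cluster_labels[rownames(gst$scores)]
  an <- anova_by_cluster(gst, cl)
  m <- ncol(gst$scores)
  expect_equal(attr(an, "threshold"), 0.05 / m)
  planted <- fx$g$truth$signature_genes$gene_id
  hit <- an$significant[an$id %in% planted]
  expect_gt(mean(hit), 0.8)
  # single-gene family: threshold is plain 0.05
  one <- gst
  one$scores <- gst$scores[, 1, drop = FALSE]
  an1 <- anova_by_cluster(one, cl)
  expect_equal(attr(an1, "threshold"), 0.05)
})

test_that("clusters below two members are excluded with a warning", {
  set.seed(30)
  scores <- matrix(rnorm(42 * 3), 42, 3,
                   dimnames = list(sprintf("S%02d", 1:42), paste0("g", 1:3)))
  gst <- structure(list(scores = scores, gene_ids = colnames(scores),
                        contributing_features = list(), class_scores = NULL),
                   class = "gene_score_table")
  cl <- c(rep(1, 20), rep(2, 21), 3)  # cluster 3 has a single member
  expect_warning(an <- anova_by_cluster(gst, cl), "excluding cluster")
  expect_identical(nlevels(attr(an, "clusters")), 2L)
  # noise samples are dropped silently
  cl2 <- c(rep(1, 20), rep(2, 20), -1, -1)
  an2 <- anova_by_cluster(gst, cl2)
  expect_identical(length(attr(an2, "clusters")), 40L)
})

test_that("Tukey pairwise calls isolate the planted cluster with signs", {
  fx <- ssvd_fixture()
  gst <- gene_scores(fx$X, fx$fit)
  cl <- fx$g$truth$cluster_labels[rownames(gst$scores)]
  an <- anova_by_cluster(gst, cl)
  pw <- tukey_pairwise(gst, cl, anova_table = an)
  expect_true(all(c("id", "cluster_a", "cluster_b", "diff", "p_adj",
                    "significant") %in% names(pw)))
  expect_true(all(pw$p_adj >= 0 & pw$p_adj <= 1))
  # for a planted exclusive gene, both pairs involving its cluster are
  # significant with a consistent sign
  sig_def <- define_signatures(pw)
  planted <- fx$g$truth$signature_genes
  called <- merge(as.data.frame(sig_def), as.data.frame(planted),
                  by.x = c("cluster", "id"), by.y = c("cluster", "gene_id"))
  expect_gt(nrow(called), 20)
  # called direction equals the sign predicted from the planted direction
  # and the learned combined loading of each gene's features
  w <- gene_scores(fx$X, fx$fit)$weights
  kinds <- stats::setNames(fx$X$features$kind, fx$X$features$feature_id)
  genes_ok <- vapply(seq_len(nrow(called)), function(i) {
    gene <- called$id[i]
    feats <- gst$contributing_features[[gene]]
    coupling <- ifelse(kinds[feats] == "METH_m", -1, 1)
    planted_dir <- if (called$direction.y[i] == "up") 1 else -1
    pred <- sign(sum(w[feats] * coupling)) * planted_dir
    (called$direction.x[i] == "up") == (pred > 0)
  }, logical(1))
  expect_gt(mean(genes_ok), 0.95)
})

test_that("exclusivity logic admits only single-cluster genes", {
  # synthetic pairwise table, 4 clusters: gene gX up in cluster 1 only;
  # gene gY significant against just 2 of 3 others; gene gZ qualifies for
  # two clusters (1 up, 2 down) and must be excluded
  mk <- function(id, a, b, diff, sig) {
    tibble::tibble(id = id, cluster_a = a, cluster_b = b, diff = diff,
                   p_adj = ifelse(sig, 1e-4, 0.5), significant = sig)
  }
  pairs <- rbind(
    mk("gX", "1", c("2", "3", "4"), c(2, 2.2, 1.9), TRUE),
    mk("gX", "2", c("3", "4"), c(0.1, -0.1), FALSE),
    mk("gX", "3", "4", -0.05, FALSE),
    mk("gY", "1", c("2", "3", "4"), c(2, 2.2, 0.1), c(TRUE, TRUE, FALSE)),
    mk("gY", "2", c("3", "4"), c(0.1, -0.1), FALSE),
    mk("gY", "3", "4", -0.05, FALSE),
    mk("gZ", "1", c("2", "3", "4"), c(2, 2.2, 1.9), TRUE),
    mk("gZ", "2", c("3", "4"), c(-2.1, -2.3), TRUE),
    mk("gZ", "3", "4", 0.05, FALSE)
  )
  sig <- define_signatures(pairs)
  expect_identical(sig$id, "gX")
  expect_identical(sig$cluster, "1")
  expect_identical(sig$direction, "up")
  # and the always-empty edge
  expect_identical(nrow(define_signatures(pairs[0, ])), 0L)
})

test_that("signatures are pairwise disjoint by construction", {
  fx <- ssvd_fixture()
  gst <- gene_scores(fx$X, fx$fit)
  cl <- fx$g$truth$cluster_labels[rownames(gst$scores)]
  sig <- define_signatures(tukey_pairwise(gst, cl))
  expect_identical(anyDuplicated(sig$id), 0L)
})

test_that("phenotype association detects planted cluster differences", {
  set.seed(13)
  cl <- rep(1:4, each = 30)
  covs <- data.frame(
    planted = c(0, 0, 0, 3)[cl] + rnorm(120),
    unrelated = rnorm(120),
    constant = rep(1, 120),
    category = sample(c("m", "f"), 120, replace = TRUE)
  )
  expect_warning(pa <- phenotype_association(covs, cl), "constant")
  om <- pa$omnibus
  expect_true(om$significant[om$covariate == "planted"])
  expect_identical(om$test[om$covariate == "category"], "chi-square")
  expect_false("constant" %in% om$covariate)
  # Dunn pairs only for the significant covariate; the extreme cluster
  # separates from every other cluster
  pw <- pa$pairwise[pa$pairwise$covariate == "planted", ]
  expect_gt(nrow(pw), 0)
  inv4 <- pw[pw$cluster_a == "4" | pw$cluster_b == "4", ]
  expect_true(all(inv4$p_adj < 0.05))
  other <- pw[pw$cluster_a != "4" & pw$cluster_b != "4", ]
  expect_true(all(other$p_adj > 0.05))
})

test_that("the Dunn z statistic matches a direct computation", {
  set.seed(14)
  x <- c(rnorm(8), rnorm(6) + 1, rnorm(7) - 0.5)
  g <- rep(c("a", "b", "c"), c(8, 6, 7))
  pw <- panomix:::dunn_pairwise(x, g)
  # independent recomputation for the (a, b) pair
  N <- length(x); r <- rank(x)
  rb <- tapply(r, g, mean); ns <- tapply(r, g, length)
  ties <- table(x)
  corr <- sum(ties^3 - ties) / (12 * (N - 1))
  z_ab <- (rb["a"] - rb["b"]) /
    sqrt((N * (N + 1) / 12 - corr) * (1 / ns["a"] + 1 / ns["b"]))
  got <- pw$z[pw$cluster_a == "a" & pw$cluster_b == "b"]
  expect_equal(got, unname(z_ab), tolerance = 1e-12)
  expect_true(all(pw$p_adj >= 0 & pw$p_adj <= 1))
})

test_that("log-rank detects a planted hazard difference and guards edges", {
  set.seed(17)
  cl <- rep(1:2, each = 50)
  haz <- c(0.1, 0.3)[cl]      # hazard ratio 3
  tt <- rexp(100, haz); cc <- rexp(100, 0.02)
  time <- pmin(tt, cc); status <- as.integer(tt <= cc)
  lr <- logrank_by_cluster(time, status, cl)
  expect_lt(lr$p_value, 0.05)
  expect_identical(lr$df, 1L)
  expect_identical(nrow(lr$medians), 2L)
  expect_error(logrank_by_cluster(time, status, rep(1, 100)), ">= 2 clusters")
  expect_error(logrank_by_cluster(c(-1, time[-1]), status, cl), "> 0")
  # a cluster with zero events stays in the test, median not reached
  status2 <- status; status2[cl == 2] <- 0
  time2 <- time; time2[cl == 2] <- max(time)  # all censored late
  lr2 <- logrank_by_cluster(time2, status2, cl)
  expect_true(is.na(lr2$medians$median[lr2$medians$cluster == "2"]))
})

test_that("over-representation ranks the matching set first", {
  universe <- paste0("g", 1:100)
  sets <- list(hit = paste0("g", 1:10), other = paste0("g", 51:70))
  res <- overrepresentation_test(paste0("g", 1:10), universe, sets)
  expect_lt(res$p_value[res$set == "hit"], 1e-10)
  expect_equal(res$p_value[res$set == "other"], 1)  # zero overlap
  expect_identical(res$overlap, c(10L, 0L))
  expect_true(all(res$p_adj >= res$p_value - 1e-15))
  expect_error(overrepresentation_test("gX", universe, sets), "subset")
  expect_error(overrepresentation_test("g1", character(0), sets), "empty")
})

test_that("random gene lists are not called enriched", {
  set.seed(31)
  universe <- paste0("g", 1:200)
  sets <- lapply(1:8, function(i) sample(universe, 25))
  names(sets) <- paste0("s", 1:8)
  frac_sig <- replicate(30, {
    res <- overrepresentation_test(sample(universe, 20), universe, sets)
    mean(res$p_adj < 0.05)
  })
  expect_gte(mean(frac_sig == 0), 0.9)
})
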