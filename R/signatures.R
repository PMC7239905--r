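#' Per-sample gene (and functional-class) scores from selected features
#'
#' For each gene with at least one selected feature, the score vector is
#' `X[, F_g] %*% w_g`, where `F_g` are the gene's selected features and
#' `w_g` the matching loading entries summed over the selected axes,
#' weighted by the axis scales `d` by default. Functional-class scores are
#' built identically over all features of the member genes. Genes with no
#' selected feature are omitted, not zero-filled.
#'
#' @param X The `extended_matrix` that was factorized (its `features`
#'   annotation supplies the feature-to-gene map).
#' @param result The `ssvd` fit of `X`.
#' @param axes Axis indices to combine; defaults to
#'   `result$selected_axes`.
#' @param weight_by_d Weight each axis' loadings by its scale `d`
#'   (default TRUE).
#' @param gene_sets Optional named list of gene-id vectors (e.g. from
#'   [read_gmt()]) for functional-class scores.
#' @return A `gene_score_table`: list with `scores` (samples x genes),
#'   `gene_ids`, `contributing_features` (named list),
#'   `class_scores` (samples x classes or NULL), `weights` (the combined
#'   per-feature loading vector).
#' @export
gene_scores <- function(X, result, axes = NULL, weight_by_d = TRUE,
                        gene_sets = NULL) {
  stopifnot(inherits(X, "extended_matrix"), inherits(result, "ssvd"))
  if (is.null(axes)) axes <- result$selected_axes
  if (length(axes) == 0) stop("no selected axes", call. = FALSE)
  W <- result$W[axes, , drop = FALSE]
  wt <- if (weight_by_d) result$d[axes] else rep(1, length(axes))
  w_comb <- as.vector(crossprod(W, wt))  # sum_k wt_k W[k, ]
  names(w_comb) <- colnames(result$W)
  sel <- result$feature_support & w_comb != 0

  feats <- X$features
  v <- X$values
  stopifnot(identical(feats$feature_id, colnames(v)))
  by_gene <- split(which(sel), feats$gene_id[sel])
  if (length(by_gene) == 0) stop("no gene has a selected feature", call. = FALSE)
  scores <- vapply(by_gene, function(cols) {
    as.vector(v[, cols, drop = FALSE] %*% w_comb[cols])
  }, numeric(nrow(v)))
  rownames(scores) <- rownames(v)

  class_scores <- NULL
  if (!is.null(gene_sets)) {
    present <- names(by_gene)
    cs <- lapply(gene_sets, function(gs) {
      cols <- unlist(by_gene[intersect(gs, present)], use.names = FALSE)
      if (length(cols) == 0) return(NULL)
      as.vector(v[, cols, drop = FALSE] %*% w_comb[cols])
    })
    cs <- cs[!vapply(cs, is.null, logical(1))]
    if (length(cs) > 0) {
      class_scores <- do.call(cbind, cs)
      rownames(class_scores) <- rownames(v)
    }
  }
  structure(
    list(
      scores = scores,
      gene_ids = names(by_gene),
      contributing_features = lapply(by_gene, function(cols) feats$feature_id[cols]),
      class_scores = class_scores,
      weights = w_comb
    ),
    class = "gene_score_table"
  )
}

#' @export
print.gene_score_table <- function(x, ...) {
  cat(sprintf("<gene_score_table> %d samples x %d genes%s\n",
              nrow(x$scores), ncol(x$scores),
              if (is.null(x$class_scores)) "" else
                sprintf(" + %d functional classes", ncol(x$class_scores))))
  invisible(x)
}

# drop noise samples and small clusters; returns list(scores, cluster factor)
align_scores_clusters <- function(scores, clusters, min_size = 2) {
  labels <- if (inherits(clusters, "cluster_assignment")) clusters$labels
            else clusters
  if (!is.null(names(labels)) && !is.null(rownames(scores))) {
    labels <- labels[rownames(scores)]
  }
  stopifnot(length(labels) == nrow(scores))
  keep <- labels != -1 & !is.na(labels)
  labels <- labels[keep]
  scores <- scores[keep, , drop = FALSE]
  sizes <- table(labels)
  small <- names(sizes)[sizes < min_size]
  if (length(small) > 0) {
    warning("excluding cluster(s) with < ", min_size, " members: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep2 <- !(labels %in% small)
    labels <- labels[keep2]
    scores <- scores[keep2, , drop = FALSE]
  }
  if (length(unique(labels)) < 2) {
    stop("need >= 2 clusters with >= ", min_size, " members", call. = FALSE)
  }
  list(scores = scores, cluster = factor(labels))
}

#' One-way ANOVA of gene (and class) scores across clusters
#'
#' Tests every gene and functional class for mean score differences across
#' clusters, with a Bonferroni family threshold of
#' `alpha_family / (number of genes + classes tested)`. Noise samples and
#' clusters with fewer than two members are excluded.
#'
#' @param table A [gene_scores()] result.
#' @param clusters A `cluster_assignment` or label vector.
#' @param alpha_family Familywise type-I error (default 0.05).
#' @return A tibble with columns `id`, `type` (`gene`/`class`),
#'   `statistic` (F), `p_value`, `significant`; the Bonferroni threshold is
#'   in attribute `"threshold"`, the cluster factor in `"clusters"`.
#' @export
anova_by_cluster <- function(table, clusters, alpha_family = 0.05) {
  stopifnot(inherits(table, "gene_score_table"))
  mats <- list(gene = table$scores)
  if (!is.null(table$class_scores)) mats$class <- table$class_scores
  m_tests <- sum(vapply(mats, ncol, integer(1)))
  threshold <- alpha_family / m_tests

  aligned <- align_scores_clusters(
    do.call(cbind, unname(mats)), clusters
  )
  cl <- aligned$cluster
  out <- purrr::map_dfr(names(mats), function(ty) {
    ids <- colnames(mats[[ty]])
    purrr::map_dfr(ids, function(id) {
      y <- aligned$scores[, id]
      fit <- stats::aov(y ~ cl)
      s <- summary(fit)[[1]]
      tibble::tibble(
        id = id, type = ty,
        statistic = s[["F value"]][1],
        p_value = s[["Pr(>F)"]][1]
      )
    })
  })
  out$significant <- out$p_value < threshold
  attr(out, "threshold") <- threshold
  attr(out, "clusters") <- cl
  attr(out, "scores") <- aligned$scores
  out
}

#' Tukey HSD pairwise comparisons for ANOVA-significant genes
#'
#' All `K (K - 1) / 2` cluster-pair comparisons per gene, with
#' Tukey-adjusted p-values and signed mean differences.
#'
#' @param table A [gene_scores()] result.
#' @param clusters A `cluster_assignment` or label vector.
#' @param gene_subset Ids to compare; default the ANOVA-significant ones
#'   from `anova_table`.
#' @param anova_table Output of [anova_by_cluster()] (recomputed when
#'   missing).
#' @param alpha_family Passed to [anova_by_cluster()] when recomputing.
#' @return Tibble with columns `id`, `cluster_a`, `cluster_b`, `diff`
#'   (mean of `a` minus mean of `b`), `p_adj`, `significant` (at 0.05,
#'   familywise within gene).
#' @export
tukey_pairwise <- function(table, clusters, gene_subset = NULL,
                           anova_table = NULL, alpha_family = 0.05) {
  stopifnot(inherits(table, "gene_score_table"))
  if (is.null(anova_table)) {
    anova_table <- anova_by_cluster(table, clusters, alpha_family)
  }
  if (is.null(gene_subset)) {
    gene_subset <- anova_table$id[anova_table$significant]
  }
  if (length(gene_subset) == 0) {
    return(tibble::tibble(id = character(), cluster_a = character(),
                          cluster_b = character(), diff = numeric(),
                          p_adj = numeric(), significant = logical()))
  }
  cl <- attr(anova_table, "clusters")
  scores <- attr(anova_table, "scores")
  purrr::map_dfr(gene_subset, function(id) {
    y <- scores[, id]
    tk <- stats::TukeyHSD(stats::aov(y ~ cl))$cl
    pair <- strsplit(rownames(tk), "-", fixed = TRUE)
    tibble::tibble(
      id = id,
      cluster_a = vapply(pair, `[`, "", 1),
      cluster_b = vapply(pair, `[`, "", 2),
      diff = tk[, "diff"],
      p_adj = tk[, "p adj"],
      significant = tk[, "p adj"] < 0.05
    )
  })
}

#' Call cluster-exclusive gene signatures
#'
#' A gene enters cluster `c`'s signature iff every pairwise comparison of
#' `c` against each other cluster is significant with a consistent sign;
#' genes qualifying for zero or for two or more clusters are excluded, so
#' signatures are pairwise disjoint by construction. Direction `up`/`down`
#' is the sign of the cluster-versus-rest mean difference.
#'
#' @param pairwise Output of [tukey_pairwise()].
#' @return A `signature_table`: tibble with columns `cluster`, `id`,
#'   `direction`, and the minimum / maximum Tukey-adjusted p among the
#'   qualifying comparisons (`min_p_adj`, `max_p_adj`).
#' @export
define_signatures <- function(pairwise) {
  empty <- tibble::tibble(cluster = character(), id = character(),
                          direction = character(), min_p_adj = numeric(),
                          max_p_adj = numeric())
  if (nrow(pairwise) == 0) {
    return(structure(empty, class = c("signature_table", class(empty))))
  }
  clusters <- sort(unique(c(pairwise$cluster_a, pairwise$cluster_b)))
  rows <- list()
  for (gene in unique(pairwise$id)) {
    pg <- pairwise[pairwise$id == gene, ]
    hits <- list()
    for (cc in clusters) {
      inv <- pg[pg$cluster_a == cc | pg$cluster_b == cc, ]
      if (nrow(inv) != length(clusters) - 1) next
      signed <- ifelse(inv$cluster_a == cc, inv$diff, -inv$diff)
      if (all(inv$significant) &&
          (all(signed > 0) || all(signed < 0))) {
        hits[[cc]] <- tibble::tibble(
          cluster = cc, id = gene,
          direction = if (signed[1] > 0) "up" else "down",
          min_p_adj = min(inv$p_adj), max_p_adj = max(inv$p_adj)
        )
      }
    }
    if (length(hits) == 1) rows[[gene]] <- hits[[1]]
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else empty
  out <- dplyr::arrange(out, .data$cluster, .data$id)
  class(out) <- c("signature_table", setdiff(class(out), "signature_table"))
  out
}

# Dunn pairwise z tests on ranks, tie-corrected, Holm-adjusted
dunn_pairwise <- function(x, g) {
  g <- factor(g)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(g)
  combs <- utils::combn(lv, 2)
  z <- apply(combs, 2, function(ab) {
    a <- ab[1]; b <- ab[2]
    (rbar[a] - rbar[b]) /
      sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[a] + 1 / ns[b]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(
    cluster_a = combs[1, ], cluster_b = combs[2, ],
    z = as.numeric(z),
    p_adj = stats::p.adjust(p, method = "holm")
  )
}

#' Associate clusters with phenotype covariates
#'
#' Numeric covariates get an omnibus Kruskal-Wallis test across clusters;
#' significant ones are followed by pairwise Dunn tests (Holm-adjusted).
#' Categorical covariates get a chi-square test of independence. Constant
#' covariates are skipped with a warning; noise samples are excluded.
#'
#' @param covariates Data frame of per-sample covariates (rownames or a
#'   `sample_id` column align samples; otherwise row order is used).
#' @param clusters A `cluster_assignment` or label vector.
#' @param alpha Omnibus significance level gating the pairwise stage
#'   (default 0.05).
#' @return List with tibbles `omnibus` (`covariate`, `statistic`, `df`,
#'   `p_value`, `test`, `significant`) and `pairwise` (`covariate`,
#'   `cluster_a`, `cluster_b`, `z`, `p_adj`).
#' @export
phenotype_association <- function(covariates, clusters, alpha = 0.05) {
  covariates <- as.data.frame(covariates)
  if ("sample_id" %in% names(covariates)) {
    rownames(covariates) <- covariates$sample_id
    covariates$sample_id <- NULL
  }
  labels <- if (inherits(clusters, "cluster_assignment")) clusters$labels
            else clusters
  if (!is.null(names(labels)) && !is.null(rownames(covariates)) &&
      all(names(labels) %in% rownames(covariates))) {
    covariates <- covariates[names(labels), , drop = FALSE]
  }
  stopifnot(nrow(covariates) == length(labels))
  keep <- labels != -1 & !is.na(labels)
  g <- factor(labels[keep])
  covariates <- covariates[keep, , drop = FALSE]

  omnibus <- list()
  pairwise <- list()
  for (nm in names(covariates)) {
    x <- covariates[[nm]]
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2) {
      warning("covariate `", nm, "` is constant; skipped", call. = FALSE)
      next
    }
    if (is.numeric(x)) {
      kw <- stats::kruskal.test(x[ok], g[ok])
      sig <- kw$p.value < alpha
      omnibus[[nm]] <- tibble::tibble(
        covariate = nm, statistic = unname(kw$statistic),
        df = unname(kw$parameter), p_value = kw$p.value,
        test = "kruskal-wallis", significant = sig
      )
      if (sig) {
        pw <- dunn_pairwise(x[ok], g[ok])
        pw$covariate <- nm
        pairwise[[nm]] <- pw[, c("covariate", "cluster_a", "cluster_b",
                                 "z", "p_adj")]
      }
    } else {
      ct <- suppressWarnings(stats::chisq.test(table(x[ok], g[ok])))
      omnibus[[nm]] <- tibble::tibble(
        covariate = nm, statistic = unname(ct$statistic),
        df = unname(ct$parameter), p_value = ct$p.value,
        test = "chi-square", significant = ct$p.value < alpha
      )
    }
  }
  list(
    omnibus = if (length(omnibus) > 0) dplyr::bind_rows(omnibus) else
      tibble::tibble(covariate = character(), statistic = numeric(),
                     df = numeric(), p_value = numeric(), test = character(),
                     significant = logical()),
    pairwise = if (length(pairwise) > 0) dplyr::bind_rows(pairwise) else
      tibble::tibble(covariate = character(), cluster_a = character(),
                     cluster_b = character(), z = numeric(), p_adj = numeric())
  )
}

#' Log-rank comparison of survival across clusters
#'
#' K-group log-rank test of the entire survival curves, with per-cluster
#' median survival. Clusters with zero events stay in the test; their
#' median is reported as `NA` (not reached). Noise samples are excluded.
#'
#' @param times Positive follow-up times.
#' @param status Event indicator (1 = event, 0 = censored).
#' @param clusters A `cluster_assignment` or label vector.
#' @return List with `statistic` (log-rank chi-square), `df`, `p_value`,
#'   and `medians`, a tibble (`cluster`, `n`, `events`, `median`).
#' @export
logrank_by_cluster <- function(times, status, clusters) {
  labels <- if (inherits(clusters, "cluster_assignment")) clusters$labels
            else clusters
  stopifnot(length(times) == length(labels), length(status) == length(labels))
  if (any(times <= 0, na.rm = TRUE)) stop("times must be > 0", call. = FALSE)
  if (!all(status %in% c(0, 1, NA))) stop("status must be 0/1", call. = FALSE)
  keep <- labels != -1 & !is.na(labels) & !is.na(times) & !is.na(status)
  g <- factor(labels[keep])
  if (nlevels(g) < 2) stop("need >= 2 clusters for the log-rank test",
                           call. = FALSE)
  tt <- times[keep]; ss <- status[keep]
  if (sum(ss) == 0) stop("no events in any cluster", call. = FALSE)
  sd_fit <- survival::survdiff(survival::Surv(tt, ss) ~ g)
  df <- length(sd_fit$n) - 1L
  sf <- survival::survfit(survival::Surv(tt, ss) ~ g)
  med <- summary(sf)$table
  medians <- tibble::tibble(
    cluster = sub("^g=", "", rownames(med)),
    n = unname(med[, "records"]),
    events = unname(med[, "events"]),
    median = unname(med[, "median"])
  )
  list(
    statistic = unname(sd_fit$chisq),
    df = df,
    p_value = stats::pchisq(sd_fit$chisq, df, lower.tail = FALSE),
    medians = medians
  )
}

#' Hypergeometric over-representation of gene sets
#'
#' Upper-tail hypergeometric test of the overlap between a gene list and
#' each gene set within a universe, with Benjamini-Hochberg adjustment.
#'
#' @param gene_list Character vector of hit genes (must be a subset of
#'   `universe`).
#' @param universe Character vector of all testable genes.
#' @param gene_sets Named list of gene-id vectors (e.g. [read_gmt()]).
#' @return Tibble with `set`, `overlap`, `set_size` (within the universe),
#'   `p_value`, `odds_ratio`, `p_adj`.
#' @export
overrepresentation_test <- function(gene_list, universe, gene_sets) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% universe)) {
    stop("gene_list must be a subset of the universe", call. = FALSE)
  }
  N <- length(universe)
  n_list <- length(gene_list)
  rows <- purrr::map_dfr(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    m <- length(set)
    k <- length(intersect(gene_list, set))
    p <- stats::phyper(k - 1, m, N - m, n_list, lower.tail = FALSE)
    or <- (k * (N - m - n_list + k)) / max((n_list - k) * (m - k), 0.5)
    tibble::tibble(set = nm, overlap = k, set_size = m,
                   p_value = p, odds_ratio = or)
  })
  rows$p_adj <- stats::p.adjust(rows$p_value, method = "BH")
  rows
}
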