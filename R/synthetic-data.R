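#' Configuration for the synthetic multi-omic generator
#'
#' Defines the study conditions emulated by [generate_multiomic()]: `L` omic
#' blocks sharing `n_samples` samples, dominant tissue-specific mean
#' structure, a small number of sparse cross-block latent factors whose
#' scores carry cluster structure, cluster-exclusive deregulated gene sets
#' with coupled expression/copy-number shifts (and opposite-sign methylation
#' shifts), missing entries, and block-specific noise.
#'
#' @param n_samples Number of samples (rows shared by all blocks).
#' @param n_tissues Number of tissue/cancer-type groups.
#' @param block_sizes Integer vector of features per block (`p_l`). Blocks
#'   are assigned kinds `GE`, `METH_m`, `CNV` in order; at most 3 blocks.
#' @param n_factors Number of sparse latent factors (0 allowed).
#' @param support_fraction Proportion of nonzero loadings per factor, in
#'   (0, 1].
#' @param factor_sd Scale of the factor-score centroids (signal scale).
#' @param tissue_sd Scale of the tissue-specific feature mean shifts.
#' @param noise_sd Residual noise standard deviation; scalar or one value
#'   per block.
#' @param n_clusters Number of planted sample clusters (each gets at least
#'   5 samples, so `n_clusters <= n_samples / 5`).
#' @param signature_size Genes per cluster-exclusive signature (0 disables
#'   signatures).
#' @param signature_effect Mean shift, in standard-deviation units, applied
#'   to a signature gene's GE and CNV features inside its cluster; its METH
#'   features receive the opposite sign. Default 1.5.
#' @param missing_fraction Proportion of entries masked missing per block,
#'   in [0, 1).
#' @param seed Integer seed; the generator is fully reproducible from it.
#'
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 120,
                         n_tissues = 3,
                         block_sizes = c(200, 300, 150),
                         n_factors = 4,
                         support_fraction = 0.05,
                         factor_sd = 1,
                         tissue_sd = 1,
                         noise_sd = 1,
                         n_clusters = 4,
                         signature_size = 10,
                         signature_effect = 1.5,
                         missing_fraction = 0,
                         seed = 1) {
  stopifnot(
    n_samples >= 1, n_tissues >= 1, length(block_sizes) >= 1,
    all(block_sizes >= 1), n_factors >= 0, n_clusters >= 1,
    signature_size >= 0, seed == round(seed)
  )
  if (length(block_sizes) > 3) {
    stop("at most 3 blocks are supported (kinds GE, METH_m, CNV)", call. = FALSE)
  }
  if (support_fraction <= 0 || support_fraction > 1) {
    stop("`support_fraction` must be in (0, 1]", call. = FALSE)
  }
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop("`missing_fraction` must be in [0, 1)", call. = FALSE)
  }
  if (n_clusters > n_samples / 5) {
    stop("`n_clusters` must be <= n_samples / 5 (>= 5 samples per cluster)",
         call. = FALSE)
  }
  n_genes <- block_sizes[1]
  if (signature_size * n_clusters > n_genes) {
    stop(sprintf(
      "block_sizes inconsistent with signatures: need %d genes for %d disjoint signatures of %d, have %d",
      signature_size * n_clusters, n_clusters, signature_size, n_genes
    ), call. = FALSE)
  }
  if (length(block_sizes) >= 3 && block_sizes[3] > n_genes) {
    stop("CNV block may not have more features than the GE block has genes",
         call. = FALSE)
  }
  if (length(block_sizes) >= 2 && block_sizes[2] > 3 * n_genes) {
    stop("METH block may map at most 3 probes per gene", call. = FALSE)
  }
  cfg <- list(
    n_samples = as.integer(n_samples), n_tissues = as.integer(n_tissues),
    block_sizes = as.integer(block_sizes), n_factors = as.integer(n_factors),
    support_fraction = support_fraction, factor_sd = factor_sd,
    tissue_sd = tissue_sd,
    noise_sd = rep_len(noise_sd, length(block_sizes)),
    n_clusters = as.integer(n_clusters),
    signature_size = as.integer(signature_size),
    signature_effect = signature_effect,
    missing_fraction = missing_fraction, seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  cfg
}

# balanced labels 1..k over n samples, shuffled
balanced_labels <- function(n, k) {
  sample(rep_len(seq_len(k), n))
}

#' Generate synthetic multi-omic data with known ground truth
#'
#' Each block is built as `X_l = tissue means + Z W_l + signature shifts +
#' noise`. Tissue membership gives every feature a tissue-specific mean
#' shift; the sparse factors `Z W` carry cluster structure (factor scores are
#' drawn around per-cluster centroids); cluster-exclusive signature genes get
#' coupled mean shifts (same sign on GE and CNV, opposite on METH); the
#' remainder is i.i.d. Gaussian noise. Genes map to one GE feature, one CNV
#' feature and 1-3 METH probes.
#'
#' @param config A [synth_config()].
#' @return A list with elements `blocks` (list of [omic_block()]) and
#'   `truth`, a list of class `synthetic_truth` with `tissue_labels`,
#'   `cluster_labels` (named integer vectors), `factor_scores` (n x K),
#'   `factor_loadings` (K x p), `support_mask` (K x p logical),
#'   `signature_genes` (tibble cluster/gene_id/direction) and
#'   `missing_masks`.
#' @export
generate_multiomic <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_samples
  L <- length(config$block_sizes)
  p_l <- config$block_sizes
  p <- sum(p_l)
  kinds <- c("GE", "METH_m", "CNV")[seq_len(L)]
  sample_ids <- sprintf("S%04d", seq_len(n))

  ## feature -> gene map
  n_genes <- p_l[1]
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  ann <- vector("list", L)
  ann[[1]] <- tibble::tibble(
    feature_id = paste0(gene_ids, "_GE"),
    gene_id = gene_ids,
    kind = "GE"
  )
  if (L >= 2) {
    # 1-3 METH probes per gene: cycle genes, capped at 3 probes each
    probe_gene <- rep(gene_ids, 3)[seq_len(p_l[2])]
    probe_gene <- sort(probe_gene)
    probe_id <- stats::ave(probe_gene, probe_gene,
                           FUN = function(g) paste0(g, "_ME", seq_along(g)))
    ann[[2]] <- tibble::tibble(feature_id = probe_id, gene_id = probe_gene,
                               kind = "METH_m")
  }
  if (L >= 3) {
    cnv_genes <- gene_ids[seq_len(p_l[3])]
    ann[[3]] <- tibble::tibble(feature_id = paste0(cnv_genes, "_CNV"),
                               gene_id = cnv_genes, kind = "CNV")
  }
  gene_chrom <- stats::setNames(
    paste0("chr", rep_len(1:22, n_genes)), gene_ids
  )

  tissue_labels <- stats::setNames(balanced_labels(n, config$n_tissues),
                                   sample_ids)
  cluster_labels <- stats::setNames(balanced_labels(n, config$n_clusters),
                                    sample_ids)

  ## sparse factor signal
  K <- config$n_factors
  Z <- matrix(0, n, K)
  W <- matrix(0, K, p)
  support <- matrix(FALSE, K, p)
  if (K > 0) {
    s <- max(1L, round(config$support_fraction * p))
    centroids <- matrix(stats::rnorm(config$n_clusters * K,
                                     sd = config$factor_sd),
                        config$n_clusters, K)
    Z <- centroids[cluster_labels, , drop = FALSE] +
      matrix(stats::rnorm(n * K, sd = 0.33 * config$factor_sd), n, K)
    for (k in seq_len(K)) {
      idx <- sample.int(p, s)
      support[k, idx] <- TRUE
      W[k, idx] <- sample(c(-1, 1), s, replace = TRUE) * stats::runif(s, 0.5, 1.5)
    }
  }
  rownames(Z) <- sample_ids

  ## cluster-exclusive signature genes
  sig <- tibble::tibble(cluster = integer(), gene_id = character(),
                        direction = character())
  shift <- matrix(0, n, p)
  feature_tbl <- dplyr::bind_rows(ann)
  if (config$signature_size > 0) {
    pool <- sample(gene_ids)
    for (cl in seq_len(config$n_clusters)) {
      genes_cl <- pool[seq_len(config$signature_size) +
                         (cl - 1) * config$signature_size]
      dir_cl <- sample(c("up", "down"), config$signature_size, replace = TRUE)
      sig <- dplyr::bind_rows(sig, tibble::tibble(
        cluster = cl, gene_id = genes_cl, direction = dir_cl
      ))
      in_cl <- cluster_labels == cl
      for (i in seq_along(genes_cl)) {
        g <- genes_cl[i]
        d <- if (dir_cl[i] == "up") 1 else -1
        cols_same <- which(feature_tbl$gene_id == g &
                             feature_tbl$kind %in% c("GE", "CNV"))
        cols_opp <- which(feature_tbl$gene_id == g &
                            feature_tbl$kind == "METH_m")
        shift[in_cl, cols_same] <- shift[in_cl, cols_same] +
          d * config$signature_effect
        shift[in_cl, cols_opp] <- shift[in_cl, cols_opp] -
          d * config$signature_effect
      }
    }
  }

  ## assemble blocks
  signal <- Z %*% W + shift
  offsets <- c(0L, cumsum(p_l))
  blocks <- vector("list", L)
  missing_masks <- vector("list", L)
  for (l in seq_len(L)) {
    cols <- (offsets[l] + 1L):offsets[l + 1L]
    tissue_means <- matrix(stats::rnorm(config$n_tissues * p_l[l],
                                        sd = config$tissue_sd),
                           config$n_tissues, p_l[l])
    X_l <- tissue_means[tissue_labels, , drop = FALSE] +
      signal[, cols, drop = FALSE] +
      matrix(stats::rnorm(n * p_l[l], sd = config$noise_sd[l]), n, p_l[l])
    rownames(X_l) <- sample_ids
    colnames(X_l) <- ann[[l]]$feature_id
    features_l <- tibble::tibble(
      feature_id = ann[[l]]$feature_id,
      gene_id = ann[[l]]$gene_id,
      chromosome = unname(gene_chrom[ann[[l]]$gene_id]),
      kind = ann[[l]]$kind
    )
    blk <- omic_block(X_l, features = features_l)
    if (config$missing_fraction > 0) {
      blk <- mask_missing(blk, config$missing_fraction,
                          seed = config$seed + 1000L * l)
    }
    missing_masks[[l]] <- blk$missing_mask
    blocks[[l]] <- blk
  }
  names(blocks) <- kinds

  colnames(W) <- feature_tbl$feature_id
  colnames(support) <- feature_tbl$feature_id
  truth <- structure(
    list(
      tissue_labels = tissue_labels,
      cluster_labels = cluster_labels,
      factor_scores = Z,
      factor_loadings = W,
      support_mask = support,
      signature_genes = sig,
      missing_masks = missing_masks
    ),
    class = "synthetic_truth"
  )
  list(blocks = blocks, truth = truth)
}

#' Mask entries of a block as missing, uniformly at random
#'
#' Exactly `round(fraction * n * p)` entries are set to `NA`.
#'
#' @param block An [omic_block()].
#' @param fraction Proportion of entries to mask, in [0, 1).
#' @param seed Integer seed; identical seeds give identical masks.
#' @return The block with `NA`s inserted and a logical `missing_mask`
#'   element (`TRUE` = masked).
#' @export
mask_missing <- function(block, fraction, seed = 1) {
  stopifnot(inherits(block, "omic_block"))
  if (fraction < 0 || fraction >= 1) {
    stop("`fraction` must be in [0, 1)", call. = FALSE)
  }
  v <- block$values
  mask <- matrix(FALSE, nrow(v), ncol(v), dimnames = dimnames(v))
  n_mask <- round(fraction * length(v))
  if (n_mask > 0) {
    set.seed(seed)
    idx <- sample.int(length(v), n_mask)
    mask[idx] <- TRUE
    v[idx] <- NA_real_
  }
  block$values <- v
  block$missing_mask <- mask
  block
}
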