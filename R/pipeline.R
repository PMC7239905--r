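#' Assemble a pipeline configuration
#'
#' Collects file paths, stage toggles and stage parameters for
#' [run_pipeline()]. Stage order is fixed: transform, QC, imputation,
#' M-value conversion, standardization/weighting, concatenation,
#' projection, sparse SVD, axis selection, embedding, clustering, gene
#' scores, signatures, phenotype and survival association.
#'
#' @param blocks Named list of block TSV paths (names become block names;
#'   kinds are taken from the annotation).
#' @param annotation Path to the feature-annotation TSV (`feature_id`,
#'   `gene_id`, `chromosome`, `kind`).
#' @param samples Path to the sample-annotation TSV (`sample_id` plus
#'   covariate columns).
#' @param out_dir Output directory (created if needed).
#' @param tissue_column Column of `samples` holding the tissue/cancer-type
#'   label used by the projection.
#' @param stages Named logical toggles: `log_ge`, `qc`, `impute`,
#'   `beta_to_m`, `project`, `embed`, `cluster`, `signatures`,
#'   `phenotypes`.
#' @param n_axes Number of sparse axes to extract; `NULL` (default) picks
#'   the rank from the recursive scree bend of the pre-projection extended
#'   matrix via [scree_rank()] (all axes above the noise floor), floored
#'   at 2.
#' @param alpha,grid_points,drop_leading,lambda Sparse-SVD settings (see
#'   [fit_ssvd()]; `lambda` fixes the penalty, `NULL` tunes it).
#' @param perplexities,tsne_iter t-SNE settings (see [tsne_embed()]).
#' @param min_pts DBSCAN core-point neighbourhood size.
#' @param qc_cv_min,qc_miss_max,impute_k QC / imputation settings.
#' @param alpha_family Familywise level for the signature ANOVA stage.
#' @param survival_columns Length-2 character vector naming the time and
#'   status columns in `samples` (`NULL` disables the log-rank stage).
#' @param seed Integer seed propagated to every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(blocks, annotation, samples, out_dir,
                            tissue_column = "tissue",
                            stages = list(),
                            n_axes = NULL, alpha = 0.5, grid_points = 50,
                            drop_leading = 0, lambda = NULL,
                            perplexities = c(10, 30), tsne_iter = 1000,
                            min_pts = 10,
                            qc_cv_min = 1, qc_miss_max = 0.20, impute_k = 3,
                            alpha_family = 0.05,
                            survival_columns = NULL,
                            seed = 1) {
  default_stages <- list(log_ge = FALSE, qc = TRUE, impute = TRUE,
                         beta_to_m = FALSE, project = TRUE, embed = TRUE,
                         cluster = TRUE, signatures = TRUE, phenotypes = TRUE)
  stages <- utils::modifyList(default_stages, stages)
  cfg <- list(
    blocks = blocks, annotation = annotation, samples = samples,
    out_dir = out_dir, tissue_column = tissue_column, stages = stages,
    n_axes = if (!is.null(n_axes)) as.integer(n_axes),
    alpha = alpha, grid_points = as.integer(grid_points),
    drop_leading = as.integer(drop_leading), lambda = lambda,
    perplexities = perplexities, tsne_iter = as.integer(tsne_iter),
    min_pts = as.integer(min_pts),
    qc_cv_min = qc_cv_min, qc_miss_max = qc_miss_max,
    impute_k = as.integer(impute_k),
    alpha_family = alpha_family, survival_columns = survival_columns,
    seed = as.integer(seed)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @return [read_pipeline_config()] returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$blocks <- as.list(raw$blocks)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage `", stage, "` failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the integration pipeline end to end
#'
#' Executes the enabled stages in their fixed order, writes every
#' intermediate artifact as TSV under the configured output directory, and
#' returns (and writes) a JSON manifest with parameters, seeds and file
#' checksums. Rerunning with the same configuration reproduces the outputs.
#'
#' @param config A [pipeline_config()], or the path to its YAML file.
#' @param truth Optional `synthetic_truth` for recovery metrics in the
#'   manifest (adjusted Rand index against planted clusters and tissues).
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(config, truth = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c(unlist(config$blocks), config$annotation, config$samples)) {
    if (!file.exists(f)) stop("configured file does not exist: ", f,
                              call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  st <- config$stages

  ann <- tibble::as_tibble(
    utils::read.delim(config$annotation, stringsAsFactors = FALSE)
  )
  samples <- utils::read.delim(config$samples, stringsAsFactors = FALSE)
  rownames(samples) <- samples$sample_id

  blocks <- stage_try("read", {
    purrr::imap(config$blocks, function(path, nm) {
      df <- utils::read.delim(path, check.names = FALSE,
                              stringsAsFactors = FALSE)
      m <- as.matrix(df[, -1, drop = FALSE])
      storage.mode(m) <- "double"
      rownames(m) <- df$sample_id
      omic_block(m, features = ann[match(colnames(m), ann$feature_id), ])
    })
  })

  if (isTRUE(st$log_ge)) {
    blocks <- stage_try("transform", {
      purrr::map(blocks, function(b) {
        if (all(b$features$kind == "GE")) log_transform_counts(b) else b
      })
    })
  }
  qc_reports <- NULL
  if (isTRUE(st$qc)) {
    res <- stage_try("qc", purrr::map(blocks, qc_filter,
                                      cv_min = config$qc_cv_min,
                                      miss_max = config$qc_miss_max))
    blocks <- purrr::map(res, "block")
    qc_reports <- purrr::map(res, "report")
    # QC can drop samples per block; re-intersect
    common <- Reduce(intersect, purrr::map(blocks, "sample_ids"))
    blocks <- purrr::map(blocks, function(b) {
      set_block_values(b, b$values[common, , drop = FALSE])
    })
  }
  if (isTRUE(st$impute)) {
    blocks <- stage_try("impute", purrr::map(blocks, knn_impute,
                                             k = config$impute_k))
  }
  if (isTRUE(st$beta_to_m)) {
    blocks <- stage_try("beta_to_m", purrr::map(blocks, function(b) {
      is_beta <- b$features$kind == "METH_beta"
      if (any(is_beta)) {
        b$values[, is_beta] <- beta_to_m(b$values[, is_beta, drop = FALSE])
        b$features$kind[is_beta] <- "METH_m"
      }
      b
    }))
  }
  blocks <- stage_try("standardize", purrr::map(blocks, standardize_and_weight))
  X <- stage_try("concatenate", concatenate_blocks(blocks))

  # rank is chosen on the pre-projection spectrum (the basis is picked
  # once for the study, then the same number of axes is extracted from the
  # projected matrix); recursive elbow keeps every bend above the noise
  # floor and later sparsity decides which axes carry signal.  Only the
  # head of the spectrum is screened: a long noise tail drags the chord
  # of the elbow heuristic.
  n_axes <- config$n_axes
  if (is.null(n_axes)) {
    sv <- svd(X$values, nu = 0, nv = 0)$d
    n_axes <- max(2L, scree_rank(utils::head(sv, 20), recursive = TRUE))
  }

  if (isTRUE(st$project)) {
    X <- stage_try("project", {
      tissue <- samples[rownames(X$values), config$tissue_column]
      apply_projection(X, build_indicator(tissue))
    })
  }

  set.seed(config$seed)
  fit <- stage_try("ssvd", fit_ssvd(
    X, n_axes = n_axes, alpha = config$alpha,
    lambda = config$lambda,
    grid = NULL
  ))
  axes <- stage_try("select_axes",
                    select_informative_axes(fit, config$drop_leading))

  write_tsv(data.frame(sample_id = rownames(fit$Z), fit$Z,
                       check.names = FALSE), out("Z.tsv"))
  write_tsv(data.frame(axis = seq_along(fit$d), d = fit$d,
                       lambda = fit$lambdas), out("d.tsv"))
  write_tsv(data.frame(feature_id = colnames(fit$W), t(fit$W),
                       check.names = FALSE), out("W.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("panomix")),
    seed = config$seed,
    n_axes = n_axes,
    parameters = unclass(config)[c("n_axes", "alpha", "grid_points",
                                   "drop_leading", "perplexities",
                                   "tsne_iter", "min_pts", "alpha_family",
                                   "tissue_column")],
    stages = st,
    pvx = fit$pvx,
    selected_axes = axes,
    n_selected_features = sum(fit$feature_support)
  )
  if (!is.null(qc_reports)) {
    manifest$qc <- purrr::map(qc_reports, function(r) {
      list(removed_features = nrow(r$removed_features),
           removed_samples = nrow(r$removed_samples))
    })
  }

  clusters <- NULL
  if (isTRUE(st$embed)) {
    emb <- stage_try("embed", tsne_embed(
      fit$Z[, axes, drop = FALSE] %*% diag(fit$d[axes], length(axes)),
      perplexities = config$perplexities,
      n_iter = config$tsne_iter, seed = config$seed
    ))
    write_tsv(data.frame(sample_id = rownames(emb$coords), emb$coords),
              out("embedding.tsv"))
    manifest$tsne <- list(perplexity = emb$perplexity, cost = emb$cost,
                          n_iter = emb$n_iter)
    if (isTRUE(st$cluster)) {
      clusters <- stage_try("cluster", dbscan_tune(emb$coords,
                                                   min_pts = config$min_pts))
      write_tsv(data.frame(sample_id = names(clusters$labels),
                           cluster = unname(clusters$labels)),
                out("clusters.tsv"))
      manifest$clustering <- list(
        eps = clusters$eps, min_pts = clusters$min_pts,
        silhouette = clusters$silhouette,
        n_clusters = clusters$n_clusters, n_noise = clusters$n_noise
      )
    }
  }

  if (isTRUE(st$signatures) && !is.null(clusters)) {
    sig_out <- stage_try("signatures", {
      gst <- gene_scores(X, fit, axes = axes)
      an <- anova_by_cluster(gst, clusters,
                             alpha_family = config$alpha_family)
      pw <- tukey_pairwise(gst, clusters, anova_table = an)
      sig <- define_signatures(pw)
      list(gst = gst, an = an, pw = pw, sig = sig)
    })
    write_tsv(data.frame(sample_id = rownames(sig_out$gst$scores),
                         sig_out$gst$scores, check.names = FALSE),
              out("gene_scores.tsv"))
    write_tsv(as.data.frame(sig_out$an[, c("id", "type", "statistic",
                                           "p_value", "significant")]),
              out("anova.tsv"))
    write_tsv(as.data.frame(sig_out$sig), out("signatures.tsv"))
    manifest$signatures <- list(
      n_genes_scored = ncol(sig_out$gst$scores),
      n_anova_significant = sum(sig_out$an$significant),
      n_signature_genes = nrow(sig_out$sig),
      anova_threshold = attr(sig_out$an, "threshold")
    )
  }

  if (isTRUE(st$phenotypes) && !is.null(clusters)) {
    pheno_cols <- setdiff(names(samples),
                          c("sample_id", config$tissue_column,
                            config$survival_columns))
    if (length(pheno_cols) > 0) {
      ph <- stage_try("phenotypes", phenotype_association(
        samples[names(clusters$labels), pheno_cols, drop = FALSE], clusters
      ))
      write_tsv(as.data.frame(ph$omnibus), out("phenotypes.tsv"))
      manifest$phenotypes <- list(
        n_tested = nrow(ph$omnibus),
        n_significant = sum(ph$omnibus$significant)
      )
    }
    if (!is.null(config$survival_columns)) {
      lr <- stage_try("survival", {
        sc <- config$survival_columns
        dat <- samples[names(clusters$labels), ]
        logrank_by_cluster(dat[[sc[1]]], dat[[sc[2]]], clusters)
      })
      write_tsv(as.data.frame(lr$medians), out("survival.tsv"))
      manifest$survival <- lr[c("statistic", "df", "p_value")]
    }
  }

  if (!is.null(truth) && !is.null(clusters)) {
    ids <- names(clusters$labels)
    manifest$recovery <- list(
      ari_clusters = adjusted_rand_index(clusters$labels,
                                         truth$cluster_labels[ids]),
      ari_tissues = adjusted_rand_index(clusters$labels,
                                        truth$tissue_labels[ids])
    )
  }

  files <- list.files(config$out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a ready-to-run synthetic fixture
#'
#' Generates a synthetic multi-omic dataset with [generate_multiomic()] and
#' writes blocks (TSV), a feature annotation (TSV), a sample table (TSV,
#' with tissue labels and cluster-linked survival columns), the ground
#' truth (JSON), the planted signatures (GMT) and a pipeline configuration
#' (YAML) into `out_dir`.
#'
#' Presets: `tiny` (120 samples, blocks of 200/300/150 features, 3 tissues
#' with strong tissue effects, 4 clusters, planted signatures, 2% missing),
#' `default` (300 samples, blocks of 400/600/300), and `null` (tiny sizes,
#' no planted factors, signatures or tissue effects).
#'
#' @param out_dir Output directory (created if needed).
#' @param preset One of `"tiny"`, `"default"`, `"null"`.
#' @param seed Integer seed for the generator and pipeline stages.
#' @return List with the `config` (also written as `config.yaml`), the
#'   `truth`, and the generator `synth_config`, invisibly.
#' @export
make_fixture <- function(out_dir, preset = c("tiny", "default", "null"),
                         seed = 42) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- switch(
    preset,
    tiny = synth_config(
      n_samples = 120, n_tissues = 3, block_sizes = c(200, 300, 150),
      n_factors = 4, support_fraction = 0.05, factor_sd = 1, tissue_sd = 3,
      noise_sd = 0.5, n_clusters = 4, signature_size = 10,
      missing_fraction = 0.02, seed = seed
    ),
    default = synth_config(
      n_samples = 300, n_tissues = 3, block_sizes = c(400, 600, 300),
      n_factors = 4, support_fraction = 0.05, factor_sd = 1, tissue_sd = 3,
      noise_sd = 0.5, n_clusters = 4, signature_size = 10,
      missing_fraction = 0.02, seed = seed
    ),
    null = synth_config(
      n_samples = 120, n_tissues = 1, block_sizes = c(200, 300, 150),
      n_factors = 0, support_fraction = 0.05, factor_sd = 1, tissue_sd = 0,
      noise_sd = 1, n_clusters = 4, signature_size = 0,
      missing_fraction = 0, seed = seed
    )
  )
  gen <- generate_multiomic(cfg)
  paths <- list()
  for (nm in names(gen$blocks)) {
    paths[[nm]] <- file.path(out_dir, paste0(nm, ".tsv"))
    write_omic_block(gen$blocks[[nm]], paths[[nm]])
  }
  ann <- dplyr::bind_rows(purrr::map(gen$blocks, "features"))
  write_tsv(as.data.frame(ann), file.path(out_dir, "features.tsv"))

  # cluster-linked survival (higher hazard in higher-numbered clusters)
  # and phenotype covariates: one tracking the clusters, one pure noise
  truth <- gen$truth
  set.seed(cfg$seed + 17L)
  n <- cfg$n_samples
  haz <- 0.1 * 1.5^(truth$cluster_labels - 1)
  time <- stats::rexp(n, haz)
  cens <- stats::rexp(n, 0.05)
  samples <- data.frame(
    sample_id = names(truth$tissue_labels),
    tissue = paste0("T", truth$tissue_labels),
    os_time = round(pmin(time, cens), 4),
    os_status = as.integer(time <= cens),
    proliferation = round(0.5 * truth$cluster_labels + stats::rnorm(n), 4),
    age = round(stats::rnorm(n, 60, 10), 1)
  )
  write_tsv(samples, file.path(out_dir, "samples.tsv"))

  jsonlite::write_json(
    list(
      preset = preset, seed = cfg$seed,
      tissue_labels = as.list(truth$tissue_labels),
      cluster_labels = as.list(truth$cluster_labels),
      signature_genes = as.data.frame(truth$signature_genes),
      support_features = purrr::map(
        seq_len(nrow(truth$support_mask)),
        function(k) colnames(truth$support_mask)[truth$support_mask[k, ]]
      )
    ),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  if (nrow(truth$signature_genes) > 0) {
    sig_sets <- split(truth$signature_genes$gene_id,
                      paste0("signature_C", truth$signature_genes$cluster))
    write_gmt(sig_sets, file.path(out_dir, "signatures.gmt"))
  }

  pcfg <- pipeline_config(
    blocks = paths,
    annotation = file.path(out_dir, "features.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    out_dir = file.path(out_dir, "results"),
    tissue_column = "tissue",
    perplexities = c(10, 30), tsne_iter = 1000,
    min_pts = 10, survival_columns = c("os_time", "os_status"),
    seed = cfg$seed
  )
  write_pipeline_config(pcfg, file.path(out_dir, "config.yaml"))
  invisible(list(config = pcfg, truth = truth, synth_config = cfg))
}
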