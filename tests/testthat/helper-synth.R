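# shared helpers for the suite

f1_score <- function(est, truth) {
  tp <- sum(est & truth)
  if (tp == 0) return(0)
  prec <- tp / sum(est)
  rec <- tp / sum(truth)
  2 * prec * rec / (prec + rec)
}

# principal angles (degrees) between the column spans of A and B
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(as.matrix(A)))
  qb <- qr.Q(qr(as.matrix(B)))
  acos(pmin(1, svd(crossprod(qa, qb))$d)) * 180 / pi
}

# a small complete block with annotation, deterministic
toy_block <- function(n = 10, p = 6, seed = 1, kind = "GE") {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%03d", seq_len(n)),
                              sprintf("f%03d", seq_len(p))))
  omic_block(m, kind = kind)
}

# the sparse-factor recovery benchmark: 3 factors, 5% support,
# noise at half the signal scale; 6 clusters excite all factor directions
support_benchmark_config <- function() {
  synth_config(
    n_samples = 150, n_tissues = 1, block_sizes = c(300, 200, 100),
    n_factors = 3, support_fraction = 0.05, factor_sd = 1,
    tissue_sd = 0, noise_sd = 0.5, n_clusters = 6,
    signature_size = 0, seed = 11
  )
}

# the signature-funnel benchmark: 3 clusters x 10 exclusive genes,
# 1.5 sd shifts, 40 samples per cluster, no latent factors
funnel_benchmark_config <- function() {
  synth_config(
    n_samples = 120, n_tissues = 1, block_sizes = c(200, 300, 150),
    n_factors = 0, support_fraction = 0.05, factor_sd = 1,
    tissue_sd = 0, noise_sd = 1, n_clusters = 3,
    signature_size = 10, signature_effect = 1.5, seed = 9
  )
}

# run the ANOVA -> Tukey -> exclusivity funnel on a gene-score matrix
run_funnel <- function(scores, clusters) {
  gst <- structure(
    list(scores = scores, gene_ids = colnames(scores),
         contributing_features = list(), class_scores = NULL),
    class = "gene_score_table"
  )
  an <- anova_by_cluster(gst, clusters)
  pw <- tukey_pairwise(gst, clusters, anova_table = an)
  define_signatures(pw)
}

standardized_extended <- function(gen) {
  concatenate_blocks(lapply(gen$blocks, standardize_and_weight))
}
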