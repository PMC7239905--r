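#' Two-dimensional t-SNE embedding with cost-based perplexity selection
#'
#' Runs t-SNE once per admissible perplexity (a perplexity is admissible
#' when `perplexity < (n - 1) / 3`) with the same seed and returns the
#' embedding with the lowest final cost (KL divergence). Inadmissible
#' perplexities are dropped with a warning; if none remain, an error
#' suggests usable values.
#'
#' @param Z Numeric matrix of per-sample scores (n x K), e.g. selected
#'   columns of an `ssvd` score matrix.
#' @param perplexities Candidate perplexities (default 50 and 100).
#' @param n_iter Gradient-descent iterations per run (default 1000).
#' @param seed Integer seed used for every run.
#' @return A `tsne_embedding`: list with `coords` (n x 2, rownames kept),
#'   `perplexity` (the winner), `cost`, `costs` (per candidate), `n_iter`,
#'   `seed`.
#' @export
tsne_embed <- function(Z, perplexities = c(50, 100), n_iter = 1000, seed = 1) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  ok <- perplexities < (n - 1) / 3
  if (any(!ok)) {
    warning("dropping perplexities ", paste(perplexities[!ok], collapse = ", "),
            " (need perplexity < (n - 1) / 3 = ", round((n - 1) / 3, 1), ")",
            call. = FALSE)
  }
  admissible <- perplexities[ok]
  if (length(admissible) == 0) {
    stop("no admissible perplexity for n = ", n,
         "; try values below ", floor((n - 1) / 3), call. = FALSE)
  }
  runs <- lapply(admissible, function(px) {
    set.seed(seed)
    Rtsne::Rtsne(Z, dims = 2, perplexity = px, max_iter = n_iter,
                 pca = FALSE, check_duplicates = FALSE, verbose = FALSE)
  })
  costs <- vapply(runs, function(r) utils::tail(r$itercosts, 1), numeric(1))
  best <- which.min(costs)
  coords <- runs[[best]]$Y
  rownames(coords) <- rownames(Z)
  colnames(coords) <- c("x", "y")
  structure(
    list(coords = coords, perplexity = admissible[best], cost = costs[best],
         costs = stats::setNames(costs, admissible),
         n_iter = as.integer(n_iter), seed = as.integer(seed)),
    class = "tsne_embedding"
  )
}

#' @export
print.tsne_embedding <- function(x, ...) {
  cat(sprintf("<tsne_embedding> %d samples, perplexity = %g, cost = %.4f\n",
              nrow(x$coords), x$perplexity, x$cost))
  invisible(x)
}

# classic DBSCAN on a precomputed distance matrix; labels: 1..K, -1 = noise
dbscan_fit <- function(d, eps, min_pts) {
  n <- nrow(d)
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  is_core <- lengths(nbrs) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !is_core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nbrs[[i]]
    while (length(queue) > 0) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == -1L) labels[j] <- cl  # noise becomes border
      if (labels[j] != 0L) next
      labels[j] <- cl
      if (is_core[j]) queue <- c(queue, nbrs[[j]])
    }
  }
  labels[labels == 0L] <- -1L
  labels
}

#' Density clustering with silhouette-tuned neighbourhood radius
#'
#' Runs DBSCAN over a grid of neighbourhood radii `eps` and keeps the
#' assignment maximizing the mean silhouette width over non-noise points
#' (computed in the embedding space); partitions with fewer than two
#' clusters score `-Inf`. Because an unconstrained silhouette favours
#' degenerate solutions that shave every cluster down to its densest core
#' (high silhouette, most samples noise), candidates leaving more than
#' `max_noise` of the samples unassigned are only considered when no
#' candidate respects the cap. Ties break toward the smallest `eps`. The
#' default grid spans 20 values between the 1st and 50th percentiles of
#' the `min_pts`-nearest-neighbour distances.
#'
#' @param coords n x 2 matrix of embedding coordinates.
#' @param eps_grid Positive increasing radii; built from the data when
#'   `NULL`.
#' @param min_pts Minimum neighbourhood size for a core point (default 10).
#' @param max_noise Largest acceptable noise fraction (default 0.2).
#' @return A `cluster_assignment`: list with `labels` (named integer,
#'   -1 = noise), `eps`, `min_pts`, `silhouette`, `n_clusters` (excluding
#'   noise), `n_noise`.
#' @export
dbscan_tune <- function(coords, eps_grid = NULL, min_pts = 10,
                        max_noise = 0.2) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2 * min_pts) {
    stop("need at least 2 * min_pts = ", 2 * min_pts, " samples", call. = FALSE)
  }
  d <- as.matrix(stats::dist(coords))
  if (is.null(eps_grid)) {
    knn_d <- apply(d, 1, function(r) sort(r)[min_pts + 1])
    lo <- max(stats::quantile(knn_d, 0.01), 1e-12)  # duplicates give 0
    hi <- stats::quantile(knn_d, 0.50)
    if (hi <= lo) hi <- lo * 1.5 + 1e-12
    eps_grid <- seq(lo, hi, length.out = 20)
  }
  stopifnot(all(eps_grid > 0), !is.unsorted(eps_grid))

  cand <- list()
  for (eps in eps_grid) {
    labels <- dbscan_fit(d, eps, min_pts)
    keep <- labels != -1L
    k <- length(unique(labels[keep]))
    if (k < 2) next
    sil <- cluster::silhouette(labels[keep], stats::as.dist(d[keep, keep]))
    cand[[length(cand) + 1L]] <- list(
      labels = labels, eps = eps,
      silhouette = mean(sil[, "sil_width"]),
      noise_frac = mean(!keep)
    )
  }
  if (length(cand) == 0) {
    stop("no eps in the grid [", signif(min(eps_grid), 3), ", ",
         signif(max(eps_grid), 3), "] yields >= 2 clusters", call. = FALSE)
  }
  ok <- vapply(cand, function(cc) cc$noise_frac <= max_noise, logical(1))
  pool <- if (any(ok)) cand[ok] else cand
  sils <- vapply(pool, `[[`, numeric(1), "silhouette")
  best <- pool[[which.max(sils)]]  # which.max: ties keep the smaller eps
  labels <- stats::setNames(best$labels, rownames(coords))
  structure(
    list(labels = labels, eps = best$eps, min_pts = as.integer(min_pts),
         silhouette = best$silhouette,
         n_clusters = length(unique(labels[labels != -1L])),
         n_noise = sum(labels == -1L)),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "<cluster_assignment> %d cluster(s), %d noise sample(s); eps = %.4g, minPts = %d, silhouette = %.3f\n",
    x$n_clusters, x$n_noise, x$eps, x$min_pts, x$silhouette
  ))
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same samples.
#' Samples labeled noise (`-1`) in either labeling are excluded before the
#' comparison, mirroring how unassigned samples are excluded from cluster
#' summaries.
#'
#' @param a,b Label vectors of equal length.
#' @param drop_noise Exclude positions labeled -1 in either vector
#'   (default TRUE).
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b, drop_noise = TRUE) {
  stopifnot(length(a) == length(b))
  if (drop_noise) {
    keep <- a != -1 & b != -1
    a <- a[keep]
    b <- b[keep]
  }
  mclust::adjustedRandIndex(a, b)
}
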