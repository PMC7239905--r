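#' Quality-control filter for an omic block
#'
#' Removes features that are all zeros, have a coefficient of variation
#' below `cv_min` percent (CV computed on observed entries as
#' `sd / |mean| * 100`; features with exactly zero mean but nonzero values
#' are kept, since the CV is undefined there), or exceed `miss_max`
#' missingness. Samples exceeding `miss_max` missingness (over the retained
#' features) are removed as well.
#'
#' @param block An [omic_block()].
#' @param cv_min CV threshold in percent (default 1).
#' @param miss_max Maximum tolerated missing proportion (default 0.20).
#' @return A list with `block` (filtered) and `report`, a `qc_report` list
#'   with tibbles `removed_features` (`feature_id`, `reason` in
#'   `all_zero` / `high_missing` / `low_cv`) and `removed_samples`.
#' @export
qc_filter <- function(block, cv_min = 1, miss_max = 0.20) {
  stopifnot(inherits(block, "omic_block"))
  v <- block$values
  if (length(v) == 0) stop("empty block", call. = FALSE)

  miss_frac <- colMeans(is.na(v))
  all_zero <- apply(v, 2, function(x) {
    obs <- x[!is.na(x)]
    length(obs) == 0 || all(obs == 0)
  })
  mu <- colMeans(v, na.rm = TRUE)
  sdev <- apply(v, 2, stats::sd, na.rm = TRUE)
  cv <- ifelse(mu == 0, Inf, abs(sdev / abs(mu)) * 100)
  cv[is.na(cv)] <- Inf

  # mutually exclusive reasons, in priority order
  reason <- rep(NA_character_, ncol(v))
  reason[all_zero] <- "all_zero"
  reason[is.na(reason) & miss_frac > miss_max] <- "high_missing"
  reason[is.na(reason) & cv < cv_min] <- "low_cv"

  removed_features <- tibble::tibble(
    feature_id = colnames(v)[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  keep_f <- is.na(reason)
  if (!any(keep_f)) {
    cond <- structure(
      class = c("panomix_qc_empty", "error", "condition"),
      list(message = "qc_filter removed every feature", call = NULL,
           report = removed_features)
    )
    stop(cond)
  }
  v2 <- v[, keep_f, drop = FALSE]
  sample_miss <- rowMeans(is.na(v2))
  keep_s <- sample_miss <= miss_max
  removed_samples <- tibble::tibble(
    sample_id = rownames(v2)[!keep_s],
    reason = rep("high_missing", sum(!keep_s))
  )
  v2 <- v2[keep_s, , drop = FALSE]

  report <- structure(
    list(removed_features = removed_features,
         removed_samples = removed_samples,
         imputation_count = NA_integer_),
    class = "qc_report"
  )
  list(block = set_block_values(block, v2), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d features removed, %d samples removed\n",
              nrow(x$removed_features), nrow(x$removed_samples)))
  if (nrow(x$removed_features) > 0) {
    print(dplyr::count(x$removed_features, .data$reason))
  }
  invisible(x)
}

#' k-nearest-neighbour imputation of missing entries
#'
#' Each missing entry is replaced by the mean of that feature over the `k`
#' samples nearest to the target sample. Distances are root mean squared
#' differences of column-standardized values over mutually observed
#' features (the mean, rather than the sum, rescales for the number of
#' mutually observed features).
#'
#' @param block An [omic_block()], possibly with `NA`s.
#' @param k Number of neighbours (default 3); must be < number of samples.
#' @return The block with all missing entries imputed.
#' @export
knn_impute <- function(block, k = 3) {
  stopifnot(inherits(block, "omic_block"))
  v <- block$values
  if (!anyNA(v)) return(block)
  n <- nrow(v)
  if (k >= n) stop("`k` must be smaller than the number of samples", call. = FALSE)
  feat_all_na <- colSums(!is.na(v)) == 0
  if (any(feat_all_na)) {
    stop("feature(s) missing in all samples (run qc_filter first): ",
         paste(utils::head(colnames(v)[feat_all_na], 5), collapse = ", "),
         call. = FALSE)
  }

  mu <- colMeans(v, na.rm = TRUE)
  sdev <- apply(v, 2, stats::sd, na.rm = TRUE)
  sdev[sdev == 0 | is.na(sdev)] <- 1
  z <- sweep(sweep(v, 2, mu, "-"), 2, sdev, "/")

  # pairwise RMS distance over mutually observed features
  zz <- z
  zz[is.na(zz)] <- 0
  obs <- !is.na(z)
  sq <- zz^2
  cross <- tcrossprod(zz)
  sums_i <- sq %*% t(obs)         # sum over mutual features of z_i^2
  sums_j <- obs %*% t(sq)
  counts <- tcrossprod(obs)
  d2 <- (sums_i + sums_j - 2 * cross) / pmax(counts, 1)
  d2[counts == 0] <- Inf
  diag(d2) <- Inf

  out <- v
  need <- which(is.na(v), arr.ind = TRUE)
  for (i in unique(need[, 1])) {
    ord <- order(d2[i, ])
    cols <- need[need[, 1] == i, 2]
    for (j in cols) {
      donors <- ord[!is.na(v[ord, j])]
      if (length(donors) == 0) {
        stop("no donor sample observed for feature ", colnames(v)[j],
             call. = FALSE)
      }
      out[i, j] <- mean(v[donors[seq_len(min(k, length(donors)))], j])
    }
  }
  block$values <- out
  block
}

#' Convert methylation beta values to M-values
#'
#' The default follows the standard M-value definition
#' `M = log2(beta / (1 - beta))`; `verbatim = TRUE` returns the plain ratio
#' `beta / (1 - beta)` without the log. Betas are clipped to
#' `[1e-6, 1 - 1e-6]` before the ratio.
#'
#' @param beta Numeric vector/matrix of beta values in [0, 1].
#' @param verbatim Use the un-logged ratio.
#' @return Object of the same shape as `beta`.
#' @export
beta_to_m <- function(beta, verbatim = FALSE) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  eps <- 1e-6
  b <- pmin(pmax(beta, eps), 1 - eps)
  r <- b / (1 - b)
  out <- if (verbatim) r else log2(r)
  if (is.matrix(beta)) {
    out <- matrix(out, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  }
  out
}

#' Collapse methylation probes to CpG islands by maximum connectivity
#'
#' For every island with more than one probe, the representative probe is
#' the one maximizing connectivity, defined as the sum of absolute Pearson
#' correlations with the island's other probes across samples. Singleton
#' islands pass through. Unmapped probes are dropped.
#'
#' @param probe_block An [omic_block()] of probe-level values (complete).
#' @param island_map Data frame with columns `probe_id`, `island_id`; each
#'   probe maps to at most one island.
#' @return An [omic_block()] with one feature per island (feature ids are
#'   island ids; `gene_id`/`chromosome` inherited from the chosen probe).
#' @export
collapse_cpg_islands <- function(probe_block, island_map) {
  stopifnot(inherits(probe_block, "omic_block"))
  island_map <- as.data.frame(island_map)
  stopifnot(all(c("probe_id", "island_id") %in% names(island_map)))
  if (anyDuplicated(island_map$probe_id)) {
    stop("each probe must map to at most one island", call. = FALSE)
  }
  v <- probe_block$values
  island_map <- island_map[island_map$probe_id %in% colnames(v), , drop = FALSE]
  islands <- split(island_map$probe_id, island_map$island_id)
  rep_probe <- character(length(islands))
  for (i in seq_along(islands)) {
    probes <- islands[[i]]
    if (length(probes) == 1) {
      rep_probe[i] <- probes
      next
    }
    sub <- v[, probes, drop = FALSE]
    sds <- apply(sub, 2, stats::sd)
    if (all(sds == 0)) {
      warning("island ", names(islands)[i],
              ": all probes have zero variance; using the first probe",
              call. = FALSE)
      rep_probe[i] <- probes[1]
      next
    }
    cm <- suppressWarnings(abs(stats::cor(sub)))
    cm[is.na(cm)] <- 0
    diag(cm) <- 0
    conn <- rowSums(cm)
    rep_probe[i] <- probes[which.max(conn)]
  }
  out <- v[, rep_probe, drop = FALSE]
  colnames(out) <- names(islands)
  old <- probe_block$features[match(rep_probe, probe_block$features$feature_id), ]
  features <- tibble::tibble(
    feature_id = names(islands),
    gene_id = old$gene_id,
    chromosome = old$chromosome,
    kind = old$kind
  )
  omic_block(out, features = features)
}

#' Log-transform count data
#'
#' Natural log of `value + pseudocount`, applied entrywise.
#'
#' @param block An [omic_block()] of nonnegative values.
#' @param pseudocount Added before the log (default 1).
#' @return The transformed block.
#' @export
log_transform_counts <- function(block, pseudocount = 1) {
  stopifnot(inherits(block, "omic_block"))
  if (any(block$values < 0, na.rm = TRUE)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  block$values <- log(block$values + pseudocount)
  block
}

#' Center, standardize, and block-weight an omic block
#'
#' Each column is centered to mean 0 and scaled to unit standard deviation
#' (denominator `n`, so the column sum of squares is exactly `n`), then all
#' entries are divided by `sqrt(p_l)` where `p_l` is the number of features
#' in the block. Every block then carries total sum of squares `n`, so
#' larger blocks do not dominate the concatenation.
#'
#' @param block A complete [omic_block()].
#' @return The standardized, weighted block.
#' @export
standardize_and_weight <- function(block) {
  stopifnot(inherits(block, "omic_block"))
  v <- block$values
  if (anyNA(v)) stop("block has missing values; impute first", call. = FALSE)
  n <- nrow(v)
  mu <- colMeans(v)
  centered <- sweep(v, 2, mu, "-")
  sd_n <- sqrt(colMeans(centered^2))
  if (any(sd_n == 0)) {
    stop("zero-variance column(s): ",
         paste(utils::head(colnames(v)[sd_n == 0], 5), collapse = ", "),
         " (qc_filter should have removed them)", call. = FALSE)
  }
  block$values <- sweep(centered, 2, sd_n, "/") / sqrt(ncol(v))
  block
}

#' Column-concatenate omic blocks into an extended matrix
#'
#' @param blocks List of complete [omic_block()]s with identical,
#'   identically ordered sample ids.
#' @return An object of class `extended_matrix`: list with `values` (n x p),
#'   `block_index` (integer per column), `p_l`, `L`, `block_names`, and the
#'   row-bound `features` annotation.
#' @export
concatenate_blocks <- function(blocks) {
  stopifnot(length(blocks) >= 1, all(vapply(blocks, inherits, TRUE, "omic_block")))
  ids <- blocks[[1]]$sample_ids
  for (l in seq_along(blocks)) {
    if (!identical(blocks[[l]]$sample_ids, ids)) {
      bad <- union(setdiff(ids, blocks[[l]]$sample_ids),
                   setdiff(blocks[[l]]$sample_ids, ids))
      if (length(bad) == 0) bad <- "(same ids, different order)"
      stop("sample ids of block ", l, " do not align with block 1: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    if (anyNA(blocks[[l]]$values)) {
      stop("block ", l, " has missing values; impute first", call. = FALSE)
    }
  }
  p_l <- vapply(blocks, function(b) ncol(b$values), integer(1))
  values <- do.call(cbind, lapply(blocks, `[[`, "values"))
  features <- dplyr::bind_rows(lapply(blocks, `[[`, "features"))
  nm <- names(blocks)
  if (is.null(nm)) nm <- paste0("block", seq_along(blocks))
  structure(
    list(
      values = values,
      block_index = rep(seq_along(blocks), p_l),
      p_l = p_l,
      L = length(blocks),
      block_names = nm,
      features = features
    ),
    class = "extended_matrix"
  )
}

#' @export
print.extended_matrix <- function(x, ...) {
  cat(sprintf("<extended_matrix> %d samples x %d features in %d block(s) [%s]\n",
              nrow(x$values), ncol(x$values), x$L,
              paste(x$p_l, collapse = ", ")))
  invisible(x)
}

#' @export
dim.extended_matrix <- function(x) dim(x$values)

# accept extended_matrix or plain matrix
as_values_matrix <- function(X) {
  if (inherits(X, "extended_matrix")) X$values
  else if (inherits(X, "omic_block")) X$values
  else if (is.matrix(X)) X
  else stop("expected a matrix, omic_block, or extended_matrix", call. = FALSE)
}
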