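#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a sparse SVD fit
#'
#' @param x An `ssvd` object.
#' @param matrix `"loadings"` (default; nonzero entries only) or
#'   `"scores"`.
#' @param ... Unused.
#' @return A tibble: loadings as `axis`, `feature_id`, `loading`; scores as
#'   `sample_id`, `axis`, `score`.
#' @method tidy ssvd
#' @export
tidy.ssvd <- function(x, matrix = c("loadings", "scores"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "loadings") {
    idx <- which(x$W != 0, arr.ind = TRUE)
    tibble::tibble(
      axis = idx[, 1],
      feature_id = colnames(x$W)[idx[, 2]],
      loading = x$W[idx]
    ) |> dplyr::arrange(.data$axis, .data$feature_id)
  } else {
    tibble::as_tibble(x$Z, .name_repair = ~ paste0("axis", seq_along(.x))) |>
      dplyr::mutate(sample_id = rownames(x$Z), .before = 1) |>
      tidyr::pivot_longer(-"sample_id", names_to = "axis",
                          names_prefix = "axis", values_to = "score",
                          names_transform = as.integer)
  }
}

#' @rdname tidy.ssvd
#' @method glance ssvd
#' @export
glance.ssvd <- function(x, ...) {
  tibble::tibble(
    n_axes = length(x$d),
    n_selected_axes = length(x$selected_axes),
    n_selected_features = sum(x$feature_support),
    pvx = x$pvx,
    alpha = x$alpha,
    converged = all(x$converged)
  )
}

#' Tidy a cluster assignment
#' @param x A `cluster_assignment`.
#' @param ... Unused.
#' @method tidy cluster_assignment
#' @export
tidy.cluster_assignment <- function(x, ...) {
  tibble::tibble(
    sample_id = names(x$labels),
    cluster = unname(x$labels),
    noise = unname(x$labels) == -1L
  )
}

#' @rdname tidy.cluster_assignment
#' @method glance cluster_assignment
#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble::tibble(
    n_clusters = x$n_clusters, n_noise = x$n_noise,
    eps = x$eps, min_pts = x$min_pts, silhouette = x$silhouette
  )
}

#' Tidy a t-SNE embedding
#' @param x A `tsne_embedding`.
#' @param ... Unused.
#' @method tidy tsne_embedding
#' @export
tidy.tsne_embedding <- function(x, ...) {
  co <- x$coords
  tibble::tibble(sample_id = rownames(co), x = co[, 1], y = co[, 2])
}

#' @rdname tidy.tsne_embedding
#' @method glance tsne_embedding
#' @export
glance.tsne_embedding <- function(x, ...) {
  tibble::tibble(perplexity = x$perplexity, cost = x$cost, n_iter = x$n_iter)
}

#' Tidy a gene score table into long form
#' @param x A `gene_score_table`.
#' @param ... Unused.
#' @method tidy gene_score_table
#' @export
tidy.gene_score_table <- function(x, ...) {
  tibble::as_tibble(x$scores) |>
    dplyr::mutate(sample_id = rownames(x$scores), .before = 1) |>
    tidyr::pivot_longer(-"sample_id", names_to = "gene_id",
                        values_to = "score")
}

#' Summarize a signature table
#' @param x A `signature_table`.
#' @param ... Unused.
#' @method glance signature_table
#' @export
glance.signature_table <- function(x, ...) {
  tibble::tibble(
    n_signature_genes = nrow(x),
    n_clusters_with_signature = dplyr::n_distinct(x$cluster),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down")
  )
}

#' Plot a t-SNE embedding, optionally colored by cluster
#'
#' @param object A `tsne_embedding`.
#' @param clusters Optional `cluster_assignment` or label vector.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tsne_embedding
#' @export
autoplot.tsne_embedding <- function(object, clusters = NULL, ...) {
  df <- tidy.tsne_embedding(object)
  if (!is.null(clusters)) {
    labels <- if (inherits(clusters, "cluster_assignment")) clusters$labels
              else clusters
    df$cluster <- factor(labels[df$sample_id], exclude = NULL)
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                     colour = .data$cluster)) +
      ggplot2::geom_point(size = 1.5) +
      ggplot2::labs(x = "tSNE 1", y = "tSNE 2", colour = "cluster") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
      ggplot2::geom_point(size = 1.5) +
      ggplot2::labs(x = "tSNE 1", y = "tSNE 2") +
      ggplot2::theme_minimal()
  }
}

#' Scree / penalty-path plot for a sparse SVD fit
#'
#' Shows the axis scale factors `d` in extraction order (scree); with
#' `type = "pvx"`, the PVX tuning path of a given axis.
#'
#' @param object An `ssvd` object.
#' @param type `"scree"` or `"pvx"`.
#' @param axis Axis whose tuning path to show (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ssvd
#' @export
autoplot.ssvd <- function(object, type = c("scree", "pvx"), axis = 1, ...) {
  type <- match.arg(type)
  if (type == "scree") {
    df <- tibble::tibble(axis = seq_along(object$d), d = object$d)
    ggplot2::ggplot(df, ggplot2::aes(.data$axis, .data$d)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "axis", y = "scale factor d") +
      ggplot2::theme_minimal()
  } else {
    path <- object$pvx_path[[axis]]
    if (is.null(path)) stop("no tuning path stored for axis ", axis,
                            call. = FALSE)
    ggplot2::ggplot(path, ggplot2::aes(.data$lambda, .data$pvx)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = expression(lambda), y = "PVX") +
      ggplot2::theme_minimal()
  }
}

#' Signature overview plot
#'
#' Bar chart of signature sizes per cluster, split by direction.
#'
#' @param object A `signature_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signature_table
#' @export
autoplot.signature_table <- function(object, ...) {
  df <- dplyr::count(tibble::as_tibble(object), .data$cluster,
                     .data$direction)
  ggplot2::ggplot(df, ggplot2::aes(.data$cluster, .data$n,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "cluster", y = "signature genes") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
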