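#' Build a one-hot membership design from group labels
#'
#' @param labels Vector of per-sample group labels (tissue, cancer type,
#'   batch, ...). Columns are ordered by first appearance.
#' @return A `projector_design`: list with `Q` (n x t indicator matrix, one
#'   1 per row) and `group_labels`.
#' @export
build_indicator <- function(labels) {
  if (length(labels) == 0) stop("no labels supplied", call. = FALSE)
  if (anyNA(labels)) stop("labels must not contain NA", call. = FALSE)
  labels <- as.character(labels)
  groups <- unique(labels)
  Q <- matrix(0, length(labels), length(groups),
              dimnames = list(names(labels), groups))
  Q[cbind(seq_along(labels), match(labels, groups))] <- 1
  structure(list(Q = Q, group_labels = groups), class = "projector_design")
}

#' @export
print.projector_design <- function(x, ...) {
  cat(sprintf("<projector_design> %d samples, %d group(s): %s\n",
              nrow(x$Q), ncol(x$Q),
              paste(utils::head(x$group_labels, 8), collapse = ", ")))
  invisible(x)
}

is_one_hot <- function(Q) {
  all(Q %in% c(0, 1)) && all(rowSums(Q) == 1)
}

#' Project out group (tissue) effects
#'
#' Premultiplies `X` by the annihilator `I - Q (Q'Q)^-1 Q'` of the
#' membership design, i.e. replaces each column by its residual after
#' removing group means. The projector is never formed densely: one-hot
#' designs use group-wise demeaning, general designs QR residualization.
#'
#' @param X An `extended_matrix`, [omic_block()], or plain matrix.
#' @param design A [build_indicator()] design, or a vector of labels
#'   (converted internally).
#' @return Object of the same class as `X` with the projected values;
#'   annotations are preserved.
#' @export
apply_projection <- function(X, design) {
  if (!inherits(design, "projector_design")) design <- build_indicator(design)
  v <- as_values_matrix(X)
  Q <- design$Q
  if (nrow(Q) != nrow(v)) {
    stop("design has ", nrow(Q), " rows but X has ", nrow(v), " samples",
         call. = FALSE)
  }
  if (is_one_hot(Q)) {
    g <- max.col(Q)
    means <- rowsum(v, g) / as.vector(table(g))
    res <- v - means[g, , drop = FALSE]
  } else {
    qr_q <- qr(Q)
    if (qr_q$rank < ncol(Q)) {
      drop_cols <- colnames(Q)[qr_q$pivot[-seq_len(qr_q$rank)]]
      if (is.null(drop_cols)) drop_cols <- qr_q$pivot[-seq_len(qr_q$rank)]
      stop("membership design is rank deficient; collinear column(s): ",
           paste(drop_cols, collapse = ", "), call. = FALSE)
    }
    res <- qr.resid(qr_q, v)
  }
  dimnames(res) <- dimnames(v)
  if (inherits(X, "extended_matrix") || inherits(X, "omic_block")) {
    X$values <- res
    X
  } else {
    res
  }
}
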