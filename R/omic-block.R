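#' Construct an omic block
#'
#' An omic block is one samples-by-features numeric matrix from a single assay
#' (gene expression, methylation, copy number), together with a per-feature
#' annotation table. Missing values (`NA`) are allowed before imputation.
#'
#' @param values Numeric matrix, samples in rows, features in columns. Row
#'   names are sample ids, column names are feature ids; both are required
#'   and must be unique.
#' @param features Data frame with one row per column of `values`, columns
#'   `feature_id`, `gene_id`, `chromosome`, `kind`. `kind` is one of
#'   `"GE"`, `"METH_beta"`, `"METH_m"`, `"CNV"`, `"other"`. If `NULL`, a
#'   minimal annotation is derived from the column names with `kind`.
#' @param kind Default feature kind used when `features` is `NULL`.
#'
#' @return An object of class `omic_block`: a list with elements `values`
#'   (numeric matrix), `sample_ids`, `features` (tibble), and optionally
#'   `missing_mask` (logical matrix set by [mask_missing()]).
#' @export
omic_block <- function(values, features = NULL, kind = "other") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x features)", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("S%04d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("f%05d", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate feature ids", call. = FALSE)
  if (is.null(features)) {
    features <- tibble::tibble(
      feature_id = colnames(values),
      gene_id = colnames(values),
      chromosome = NA_character_,
      kind = kind
    )
  }
  features <- tibble::as_tibble(features)
  required <- c("feature_id", "gene_id", "chromosome", "kind")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols) > 0) {
    stop("`features` lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(features$feature_id, colnames(values))) {
    stop("`features$feature_id` must match colnames(values) in order", call. = FALSE)
  }
  ok_kinds <- c("GE", "METH_beta", "METH_m", "CNV", "other")
  if (!all(features$kind %in% ok_kinds)) {
    stop("feature `kind` must be one of ", paste(ok_kinds, collapse = ", "),
         call. = FALSE)
  }
  beta_cols <- which(features$kind == "METH_beta")
  if (length(beta_cols) > 0) {
    b <- values[, beta_cols, drop = FALSE]
    if (any(b < 0 | b > 1, na.rm = TRUE)) {
      stop("METH_beta values must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(
      values = values,
      sample_ids = rownames(values),
      features = features
    ),
    class = "omic_block"
  )
}

#' @export
print.omic_block <- function(x, ...) {
  n_na <- sum(is.na(x$values))
  cat(sprintf(
    "<omic_block> %d samples x %d features (%s)%s\n",
    nrow(x$values), ncol(x$values),
    paste(unique(x$features$kind), collapse = "/"),
    if (n_na > 0) sprintf(", %d missing", n_na) else ""
  ))
  invisible(x)
}

#' @export
dim.omic_block <- function(x) dim(x$values)

# replace the value matrix, keeping annotation consistent (columns may be
# dropped/reordered; rows may be dropped)
set_block_values <- function(block, values) {
  keep <- match(colnames(values), block$features$feature_id)
  stopifnot(!anyNA(keep))
  block$values <- values
  block$sample_ids <- rownames(values)
  block$features <- block$features[keep, , drop = FALSE]
  if (!is.null(block$missing_mask)) {
    block$missing_mask <-
      block$missing_mask[rownames(values), colnames(values), drop = FALSE]
  }
  block
}

#' Read / write an omic block as TSV
#'
#' Matrix layout: header row of feature ids, first column `sample_id`,
#' tab-separated. Annotation layout: columns `feature_id`, `gene_id`,
#' `chromosome`, `kind`.
#'
#' @param path TSV file with the value matrix.
#' @param annotation_path Optional TSV file with the feature annotation.
#' @param kind Default kind when no annotation file is given.
#' @return [read_omic_block()] returns an `omic_block`;
#'   [write_omic_block()] returns `path` invisibly.
#' @export
read_omic_block <- function(path, annotation_path = NULL, kind = "other") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id") {
    stop("first column of ", path, " must be `sample_id`", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$sample_id
  features <- NULL
  if (!is.null(annotation_path)) {
    features <- tibble::as_tibble(
      utils::read.delim(annotation_path, stringsAsFactors = FALSE)
    )
    features <- features[match(colnames(m), features$feature_id), , drop = FALSE]
  }
  omic_block(m, features = features, kind = kind)
}

#' @rdname read_omic_block
#' @param block An `omic_block`.
#' @export
write_omic_block <- function(block, path, annotation_path = NULL) {
  df <- data.frame(sample_id = rownames(block$values),
                   block$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path)) {
    utils::write.table(block$features, annotation_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return [read_gmt()] returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets Named list of character vectors of gene ids.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(
    names(sets),
    function(nm) paste(c(nm, "na", sets[[nm]]), collapse = "\t"),
    character(1)
  )
  writeLines(lines, path)
  invisible(path)
}
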