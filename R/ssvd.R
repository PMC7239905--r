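#' Elastic-net thresholding operator
#'
#' Soft-thresholds `w` at `lambda * alpha` and shrinks by the ridge part of
#' the penalty. The default denominator `1 + lambda * (1 - alpha)` is the
#' exact minimizer of the one-dimensional proximal objective
#' `0.5 (x - w)^2 + lambda * alpha * |x| + 0.5 * lambda * (1 - alpha) * x^2`.
#' `verbatim = TRUE` instead divides by `lambda * (1 - alpha)` (an
#' alternative scaling that is undefined when `lambda * (1 - alpha) = 0`).
#'
#' @param w Numeric vector (the unpenalized update).
#' @param lambda Penalty level, >= 0.
#' @param alpha Elastic-net mixing parameter in [0, 1] (1 = pure lasso).
#' @param verbatim Use the `lambda * (1 - alpha)` denominator.
#' @return Thresholded vector, same shape as `w`.
#' @export
en_threshold <- function(w, lambda, alpha, verbatim = FALSE) {
  stopifnot(lambda >= 0, alpha >= 0, alpha <= 1)
  soft <- sign(w) * pmax(abs(w) - lambda * alpha, 0)
  if (verbatim) {
    denom <- lambda * (1 - alpha)
    if (denom == 0) {
      stop("verbatim thresholding divides by lambda * (1 - alpha) = 0; ",
           "use lambda > 0 and alpha < 1, or verbatim = FALSE", call. = FALSE)
    }
    soft / denom
  } else {
    soft / (1 + lambda * (1 - alpha))
  }
}

# leading left singular vector, deterministic. Small problems use LAPACK
# (exact; keeps the unpenalized path at machine precision even when the
# leading singular values nearly tie); large ones a fixed-start power
# iteration with no RNG.
leading_left_sv <- function(X, tol = 1e-6, max_iter = 100) {
  if (length(X) <= 2e5) {
    z <- svd(X, nu = 1, nv = 0)$u[, 1]
    if (z[which.max(abs(z))] < 0) z <- -z
    return(z)
  }
  # fixed generic start (column sums vanish on centered data)
  w <- sin(seq_len(ncol(X)))
  w <- w / sqrt(sum(w^2))
  z <- rep(0, nrow(X))
  for (i in seq_len(max_iter)) {
    z_new <- as.vector(X %*% w)
    nz <- sqrt(sum(z_new^2))
    if (nz == 0) break
    z_new <- z_new / nz
    w <- as.vector(crossprod(X, z_new))
    w <- w / sqrt(sum(w^2))
    if (sqrt(sum((z_new - z)^2)) < tol) {
      z <- z_new
      break
    }
    z <- z_new
  }
  if (z[which.max(abs(z))] < 0) z <- -z
  z
}

#' Rank-1 sparse SVD by alternating thresholded power iterations
#'
#' Minimizes `||X - d z w'||_F^2 + lambda (alpha ||w||_1 + (1-alpha)
#' ||w||_2^2)` over unit-norm `z` and sparse `w` by alternating
#' `z <- X w / ||X w||` and `w <- en_threshold(X' z, lambda, alpha)`,
#' starting from the unpenalized leading singular vector. On return `w` has
#' unit norm (when nonzero) with the scale absorbed into `d = z' X w`.
#'
#' @param X Numeric matrix (complete, finite), or `extended_matrix`.
#' @param lambda Penalty level.
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @param tol Convergence tolerance on the joint relative change of `z` and
#'   `w` (default 1e-8).
#' @param max_iter Maximum iterations (default 500).
#' @param verbatim Passed to [en_threshold()].
#' @param w_init Optional warm-start loading vector.
#' @param z_init Optional starting score vector (unit norm); computed from
#'   the data when neither `w_init` nor `z_init` is given.
#' @return A `rank1_factor`: list with `d`, `z` (unit norm), `w` (unit norm,
#'   exactly zero off-support), `lambda`, `alpha`, `n_iter`, `converged`.
#' @export
rank1_ssvd <- function(X, lambda, alpha = 0.5, tol = 1e-8, max_iter = 500,
                       verbatim = FALSE, w_init = NULL, z_init = NULL) {
  v <- as_values_matrix(X)
  if (anyNA(v) || any(!is.finite(v))) {
    stop("X must be complete and finite", call. = FALSE)
  }
  n <- nrow(v); p <- ncol(v)
  zero_factor <- function(iter) {
    structure(list(d = 0, z = rep(0, n), w = rep(0, p), lambda = lambda,
                   alpha = alpha, n_iter = iter, converged = TRUE),
              class = "rank1_factor")
  }
  if (sqrt(sum(v^2)) < 1e-12) return(zero_factor(0L))

  if (!is.null(w_init) && sqrt(sum(w_init^2)) > 0) {
    zr <- v %*% (w_init / sqrt(sum(w_init^2)))
    nz <- sqrt(sum(zr^2))
    z <- if (nz > 0) as.vector(zr) / nz else leading_left_sv(v)
  } else if (!is.null(z_init)) {
    z <- z_init / sqrt(sum(z_init^2))
  } else {
    z <- leading_left_sv(v)
  }
  w <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    w_new <- en_threshold(as.vector(crossprod(v, z)), lambda, alpha,
                          verbatim = verbatim)
    nw <- sqrt(sum(w_new^2))
    if (nw == 0) return(zero_factor(iter))
    w_unit <- w_new / nw
    zr <- v %*% w_new
    nz <- sqrt(sum(zr^2))
    if (nz == 0) return(zero_factor(iter))
    z_new <- as.vector(zr) / nz
    delta <- max(sqrt(sum((z_new - z)^2)),
                 sqrt(sum((w_unit - w)^2)))
    z <- z_new
    w <- w_unit
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  d <- as.numeric(crossprod(z, v %*% w))
  if (d < 0) {  # orient so the scale is nonnegative
    z <- -z
    d <- -d
  }
  structure(list(d = d, z = z, w = w, lambda = lambda, alpha = alpha,
                 n_iter = iter, converged = converged),
            class = "rank1_factor")
}

#' @export
print.rank1_factor <- function(x, ...) {
  cat(sprintf("<rank1_factor> d = %.4g, support = %d, lambda = %.4g (%s in %d it.)\n",
              x$d, sum(x$w != 0), x$lambda,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Subtract a rank-1 factor from a matrix
#'
#' @param X Matrix (or `extended_matrix`).
#' @param factor A `rank1_factor`.
#' @return `X - d z w'`, same class as the input values.
#' @export
deflate <- function(X, factor) {
  v <- as_values_matrix(X)
  res <- v - factor$d * tcrossprod(factor$z, factor$w)
  if (inherits(X, "extended_matrix")) {
    X$values <- res
    X
  } else res
}

#' Proportion of variance of X explained by a factorization
#'
#' `1 - ||X - Z diag(d) W||_F^2 / ||X||_F^2`. If `d` is omitted, `Z W` is
#' used as the reconstruction directly.
#'
#' @param X Matrix (or `extended_matrix`).
#' @param Z n x K score matrix.
#' @param W K x p loading matrix.
#' @param d Optional length-K scale vector.
#' @return A proportion in [0, 1] (up to solver tolerance).
#' @export
pvx <- function(X, Z, W, d = NULL) {
  v <- as_values_matrix(X)
  total <- sum(v^2)
  if (total == 0) stop("||X|| = 0: PVX undefined", call. = FALSE)
  Z <- as.matrix(Z); W <- as.matrix(W)
  recon <- if (is.null(d)) Z %*% W else Z %*% (d * W)
  1 - sum((v - recon)^2) / total
}

#' Build a penalty grid
#'
#' Log-spaced decreasing sequence from `lambda_max` (the smallest penalty
#' that zeroes every loading at the first iteration, `max |X'z0| / alpha`)
#' down to `lambda_max * 1e-4`.
#'
#' @param X Matrix (or `extended_matrix`).
#' @param alpha Elastic-net mixing parameter.
#' @param n_points Number of grid points (default 50, minimum 5).
#' @param log_scale Log-spaced (default) or linear.
#' @param z0 Optional precomputed leading left singular vector.
#' @return A `lambda_grid`: list with `values` (decreasing), `n_points`,
#'   `log_scale`.
#' @export
lambda_grid <- function(X, alpha = 0.5, n_points = 50, log_scale = TRUE,
                        z0 = NULL) {
  stopifnot(n_points >= 5)
  v <- as_values_matrix(X)
  if (is.null(z0)) z0 <- leading_left_sv(v)
  a <- max(alpha, 1e-3)
  lambda_max <- max(abs(crossprod(v, z0))) / a
  if (lambda_max <= 0) stop("X appears to be zero; no grid", call. = FALSE)
  vals <- if (log_scale) {
    exp(seq(log(lambda_max), log(lambda_max * 1e-4), length.out = n_points))
  } else {
    seq(lambda_max, lambda_max * 1e-4, length.out = n_points)
  }
  structure(list(values = vals, n_points = as.integer(n_points),
                 log_scale = log_scale),
            class = "lambda_grid")
}

#' Pick the penalty at the sharpest drop of the PVX curve
#'
#' Estimates the discrete second derivative of PVX with respect to the
#' penalty (central differences on the actual, possibly log-scaled,
#' spacing) and returns the interior grid point minimizing it — the point
#' of steepest downward bend, where further penalization starts discarding
#' informative features. Ties break toward larger penalties (sparser
#' models); endpoints are never candidates. Because the curvature of a
#' smooth PVX path is also extreme where the penalty has already wiped
#' out nearly the whole factor, grid points explaining less than
#' `min_pvx_frac` of the path's maximum PVX are not candidates (unless no
#' point qualifies, in which case all interior points compete).
#'
#' @param pvx_values PVX per grid point, aligned with `lambdas`.
#' @param lambdas Penalty values (any order; need not be equispaced). A
#'   plain index grid `seq_along(pvx_values)` works for unit spacing.
#' @param log_scale Differentiate on `log(lambda)` spacing (default FALSE
#'   when `lambdas` contains zeros or is an index grid).
#' @param min_pvx_frac Degeneracy floor as a fraction of the maximum PVX
#'   on the path (default 0.25).
#' @return List with `lambda`, `index` (into the input order), and
#'   `curvature` (the second-derivative estimates, NA at endpoints).
#' @export
pick_lambda <- function(pvx_values, lambdas, log_scale = FALSE,
                        min_pvx_frac = 0.25) {
  stopifnot(length(pvx_values) == length(lambdas), length(lambdas) >= 3)
  ord <- order(lambdas)
  lam <- lambdas[ord]
  pv <- pvx_values[ord]
  x <- if (log_scale) log(lam) else lam
  m <- length(pv)
  d2 <- rep(NA_real_, m)
  for (i in 2:(m - 1)) {
    h1 <- x[i] - x[i - 1]
    h2 <- x[i + 1] - x[i]
    d2[i] <- ((pv[i + 1] - pv[i]) / h2 - (pv[i] - pv[i - 1]) / h1) /
      ((h1 + h2) / 2)
  }
  cand <- which(!is.na(d2) & pv >= min_pvx_frac * max(pv))
  if (length(cand) == 0) cand <- which(!is.na(d2))
  best_val <- min(d2[cand])
  best <- cand[d2[cand] <= best_val + 1e-12]
  i_star <- max(best)  # largest lambda among ties
  idx <- ord[i_star]
  curv <- rep(NA_real_, m)
  curv[ord] <- d2
  list(lambda = lambdas[idx], index = idx, curvature = curv)
}

#' Tune the sparsity penalty on a PVX path
#'
#' Fits the rank-1 sparse factorization at every grid penalty (warm-started
#' from large to small), records PVX, warns if PVX fails to be monotone
#' beyond `1e-9`, and picks the penalty with [pick_lambda()].
#'
#' @param X Matrix (or `extended_matrix`).
#' @param grid A [lambda_grid()]; built automatically when `NULL`.
#' @param alpha Elastic-net mixing parameter.
#' @param ... Passed to [rank1_ssvd()] (`tol`, `max_iter`, `verbatim`).
#' @return List with `lambda` (chosen), `pvx_path` (tibble `lambda`, `pvx`,
#'   `support`), and `grid`.
#' @export
tune_lambda <- function(X, grid = NULL, alpha = 0.5, ...) {
  v <- as_values_matrix(X)
  z0 <- leading_left_sv(v)
  if (is.null(grid)) grid <- lambda_grid(v, alpha = alpha, z0 = z0)
  stopifnot(inherits(grid, "lambda_grid"))
  lams <- sort(grid$values, decreasing = TRUE)
  pv <- numeric(length(lams))
  supp <- integer(length(lams))
  w_prev <- NULL
  for (i in seq_along(lams)) {
    f <- rank1_ssvd(v, lams[i], alpha = alpha, w_init = w_prev, z_init = z0,
                    ...)
    pv[i] <- pvx(v, matrix(f$z), matrix(f$w, nrow = 1), d = f$d)
    supp[i] <- sum(f$w != 0)
    if (f$d > 0) w_prev <- f$w
  }
  # pv runs from sparsest (large lambda) to densest: should be non-decreasing
  if (any(diff(pv) < -1e-9)) {
    warning("PVX is not monotone in lambda beyond tolerance (solver noise)",
            call. = FALSE)
  }
  choice <- pick_lambda(pv, lams, log_scale = grid$log_scale)
  list(
    lambda = choice$lambda,
    pvx_path = tibble::tibble(lambda = lams, pvx = pv, support = supp),
    grid = grid
  )
}

# single-elbow pass: rank and bend strength of one scree segment
scree_elbow <- function(s) {
  m <- length(s)
  x <- (seq_len(m) - 1) / (m - 1)
  y <- (s - s[m]) / (s[1] - s[m])
  chord <- 1 - x
  elev <- y - chord
  strength <- max(abs(elev[2:(m - 1)]))
  if (max(elev[2:(m - 1)]) > 1e-12) {
    rank <- as.integer(which.max(replace(elev, c(1, m), -Inf)))
  } else {
    knee <- which.min(replace(elev, c(1, m), Inf))
    rank <- max(1L, as.integer(knee) - 1L)
  }
  list(rank = rank, strength = strength)
}

#' Choose a rank from a scree curve
#'
#' Elbow heuristic on the min-max normalized scree: the rank is the index
#' maximizing the perpendicular elevation above the chord joining the first
#' and last points (the last component before the drop). If no point rises
#' above the chord (a convex scree), the knee is the point of maximum sag
#' below the chord and the rank is the index before it.
#'
#' A spectrum can hold several bends at different scales (for example a
#' pair of dominant tissue axes far above a shelf of weaker structure that
#' itself drops to a noise floor). With `recursive = TRUE` the elbow
#' search is repeated on the remainder of the curve past the previous
#' elbow until no clear bend is left, returning the last bend before the
#' noise floor — the reading under which every axis above the floor is
#' retained and downstream sparsity decides which of them carry signal.
#'
#' @param singular_values Decreasing nonnegative sequence, length >= 3.
#' @param rank Optional explicit override, returned as-is.
#' @param recursive Keep descending past earlier elbows (default FALSE).
#' @param min_strength Bend strength (max |chord elevation| of the
#'   normalized segment) below which a segment counts as flat and the
#'   recursion stops (default 0.3).
#' @return Integer rank.
#' @export
scree_rank <- function(singular_values, rank = NULL, recursive = FALSE,
                       min_strength = 0.3) {
  if (!is.null(rank)) return(as.integer(rank))
  s <- as.numeric(singular_values)
  stopifnot(length(s) >= 3)
  if (diff(range(s)) < 1e-12) {
    warning("constant spectrum: no bend; returning rank 1", call. = FALSE)
    return(1L)
  }
  m <- length(s)
  first <- scree_elbow(s)
  if (!recursive) return(first$rank)
  total_range <- s[1] - s[m]
  rank_out <- first$rank
  repeat {
    start <- rank_out + 1L
    if (m - start + 1L < 3L) break
    sub <- s[start:m]
    if ((sub[1] - sub[length(sub)]) / total_range < 0.05) break
    e <- scree_elbow(sub)
    if (e$strength < min_strength) break
    rank_out <- rank_out + e$rank
  }
  as.integer(rank_out)
}

#' Fit a multi-axis sparse SVD by deflation
#'
#' Extracts `n_axes` rank-1 factors sequentially: per axis, optionally
#' tunes the penalty on the current residual ([tune_lambda()]), fits
#' [rank1_ssvd()], and deflates. Axes are returned in extraction order
#' (decreasing explained variance for reasonable penalties).
#'
#' @param X `extended_matrix` or plain matrix (already preprocessed /
#'   projected).
#' @param n_axes Number of axes to extract.
#' @param grid A [lambda_grid()] used for tuning (rebuilt per residual when
#'   `NULL`).
#' @param alpha Elastic-net mixing parameter; 0.5 gives equal lasso and
#'   ridge contributions.
#' @param lambda Optional fixed penalty (scalar or per-axis vector); when
#'   supplied, tuning is skipped.
#' @param tol,max_iter,verbatim Passed to [rank1_ssvd()].
#' @return An `ssvd` object: list with `Z` (n x K), `W` (K x p), `d`,
#'   `lambdas`, `alpha`, `pvx_path` (list of per-axis tuning tibbles),
#'   `selected_axes` (axes with any nonzero loading), `feature_support`
#'   (logical per feature: nonzero in >= 1 selected axis), `pvx` (of the
#'   full fit), `converged`.
#' @export
fit_ssvd <- function(X, n_axes, grid = NULL, alpha = 0.5, lambda = NULL,
                     tol = 1e-8, max_iter = 500, verbatim = FALSE) {
  v <- as_values_matrix(X)
  n <- nrow(v); p <- ncol(v)
  if (n_axes > min(n, p)) {
    stop("n_axes must be <= min(n, p) = ", min(n, p), call. = FALSE)
  }
  if (!is.null(lambda)) lambda <- rep_len(lambda, n_axes)
  Z <- matrix(0, n, n_axes, dimnames = list(rownames(v), NULL))
  W <- matrix(0, n_axes, p, dimnames = list(NULL, colnames(v)))
  d <- numeric(n_axes)
  lambdas <- numeric(n_axes)
  paths <- vector("list", n_axes)
  converged <- logical(n_axes)
  res <- v
  for (k in seq_len(n_axes)) {
    if (sqrt(sum(res^2)) < 1e-10 * max(1, sqrt(sum(v^2)))) {
      # residual exhausted: remaining axes are zero factors
      lambdas[k] <- if (!is.null(lambda)) lambda[k] else 0
      converged[k] <- TRUE
      next
    }
    if (is.null(lambda)) {
      tuned <- tune_lambda(res, grid = grid, alpha = alpha, tol = tol,
                           max_iter = max_iter, verbatim = verbatim)
      lam_k <- tuned$lambda
      paths[[k]] <- tuned$pvx_path
    } else {
      lam_k <- lambda[k]
    }
    f <- rank1_ssvd(res, lam_k, alpha = alpha, tol = tol,
                    max_iter = max_iter, verbatim = verbatim)
    Z[, k] <- f$z
    W[k, ] <- f$w
    d[k] <- f$d
    lambdas[k] <- lam_k
    converged[k] <- f$converged
    res <- res - f$d * tcrossprod(f$z, f$w)
  }
  support_by_axis <- W != 0
  selected <- which(rowSums(support_by_axis) > 0)
  structure(
    list(
      Z = Z, W = W, d = d, lambdas = lambdas, alpha = alpha,
      pvx_path = paths,
      selected_axes = selected,
      feature_support = colSums(support_by_axis[selected, , drop = FALSE]) > 0,
      pvx = pvx(v, Z, W, d = d),
      converged = converged
    ),
    class = "ssvd"
  )
}

#' @export
print.ssvd <- function(x, ...) {
  cat(sprintf(
    "<ssvd> %d axes (%d with support), %d/%d features selected, PVX = %.3f\n",
    length(x$d), length(x$selected_axes), sum(x$feature_support),
    length(x$feature_support), x$pvx
  ))
  invisible(x)
}

#' Select informative (sparse, nonempty) axes
#'
#' Returns the axes that retained at least one nonzero loading, after
#' optionally dropping the `drop_leading` largest-variance axes (useful
#' when the leading axes carry broad structure not of interest). Order is
#' by explained variance (`d`, decreasing).
#'
#' @param result An `ssvd` fit.
#' @param drop_leading Number of leading (largest `d`) axes to drop.
#' @return Integer vector of axis indices.
#' @export
select_informative_axes <- function(result, drop_leading = 0) {
  stopifnot(inherits(result, "ssvd"))
  ord <- order(result$d, decreasing = TRUE)
  if (drop_leading > 0) ord <- ord[-seq_len(min(drop_leading, length(ord)))]
  keep <- ord[ord %in% result$selected_axes & result$d[ord] > 0]
  if (length(keep) == 0) {
    stop("no informative axes survive; refit with a smaller penalty ",
         "or smaller drop_leading", call. = FALSE)
  }
  keep
}
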