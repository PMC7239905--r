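test_that("en_threshold matches its closed form in both modes", {
  expect_identical(en_threshold(0.05, 0.2, 0.5), 0)       # dead zone
  expect_equal(en_threshold(0.5, 0.2, 0.5), 0.4 / 1.1)    # shrink + scale
  expect_equal(en_threshold(-0.5, 0.2, 0.5), -0.4 / 1.1)  # odd symmetry
  w <- c(-2, -0.1, 0, 0.3, 5)
  expect_identical(en_threshold(w, 0, 0.5), w)            # no penalty
  expect_equal(en_threshold(0.5, 0.2, 0.5, verbatim = TRUE), 0.4 / 0.1)
  expect_error(en_threshold(0.5, 0.2, 1, verbatim = TRUE), "verbatim")
  expect_error(en_threshold(0.5, 0, 0.5, verbatim = TRUE), "verbatim")
})

test_that("the unpenalized rank-1 fit is the leading singular triplet", {
  set.seed(1)
  X <- matrix(rnorm(30 * 50), 30, 50)
  f <- rank1_ssvd(X, lambda = 0)
  sv <- svd(X)
  s <- sign(sum(f$z * sv$u[, 1]))
  expect_lt(max(abs(f$z - s * sv$u[, 1])), 1e-8)
  expect_lt(max(abs(f$w - s * sv$v[, 1])), 1e-8)
  expect_equal(f$d, sv$d[1], tolerance = 1e-10)
})

test_that("exact rank-1 structure yields exact support recovery", {
  set.seed(2)
  u <- rnorm(40)
  v <- numeric(60)
  v[c(3, 17, 41, 55)] <- c(2, -1.5, 1, 3)
  X <- u %*% t(v)
  f <- rank1_ssvd(X, lambda = 0.05)
  expect_setequal(which(f$w != 0), c(3, 17, 41, 55))
  f2 <- rank1_ssvd(X, lambda = 1e6)
  expect_identical(f2$d, 0)
  expect_identical(sum(f2$w != 0), 0L)
})

test_that("deflation obeys its algebraic identities", {
  set.seed(3)
  X <- matrix(rnorm(20 * 15), 20, 15)
  f <- rank1_ssvd(X, lambda = 0)
  res <- deflate(X, f)
  expect_equal(sum(X^2) - sum(res^2), f$d^2, tolerance = 1e-6)

  u <- rnorm(10); v <- rnorm(8)
  R1 <- u %*% t(v)
  fr <- rank1_ssvd(R1, lambda = 0)
  expect_lt(max(abs(deflate(R1, fr))), 1e-7)

  zf <- rank1_ssvd(matrix(0, 5, 4), lambda = 1)
  expect_identical(deflate(X[1:5, 1:4], zf), X[1:5, 1:4])
})

test_that("pvx matches closed forms from a known spectrum", {
  set.seed(4)
  # build X with singular values 3, 2, 1
  Q1 <- qr.Q(qr(matrix(rnorm(12 * 3), 12, 3)))
  Q2 <- qr.Q(qr(matrix(rnorm(9 * 3), 9, 3)))
  X <- Q1 %*% diag(c(3, 2, 1)) %*% t(Q2)
  sv <- svd(X)
  expect_equal(pvx(X, sv$u, t(sv$v), d = sv$d), 1, tolerance = 1e-12)
  expect_equal(pvx(X, matrix(0, 12, 1), matrix(0, 1, 9)), 0)
  expect_equal(
    pvx(X, sv$u[, 1, drop = FALSE], t(sv$v)[1, , drop = FALSE],
        d = sv$d[1]),
    9 / 14, tolerance = 1e-12
  )
  expect_error(pvx(matrix(0, 3, 3), matrix(0, 3, 1), matrix(0, 1, 3)),
               "undefined")
})

test_that("pick_lambda finds the drop and breaks ties toward sparsity", {
  res <- pick_lambda(c(0.9, 0.9, 0.9, 0.2, 0.1), 1:5)
  expect_identical(res$index, 3L)
  expect_identical(res$lambda, 3L)
  # linear PVX: curvature ~ 0 everywhere; tie-break -> largest interior
  lin <- pick_lambda(seq(1, 0.5, length.out = 7), 1:7)
  expect_identical(lin$index, 6L)
})

test_that("PVX is monotone on the tuning grid and support shrinks with lambda", {
  set.seed(5)
  X <- matrix(rnorm(60 * 150), 60, 150)
  tuned <- tune_lambda(X)
  path <- tuned$pvx_path  # ordered by decreasing lambda
  expect_true(all(diff(path$pvx) >= -1e-9))       # pvx grows as lambda falls
  expect_true(all(diff(path$support) >= 0))        # support likewise
  expect_true(tuned$lambda %in% path$lambda)
})

test_that("scree_rank finds bends, with overrides and degenerate paths", {
  expect_identical(scree_rank(c(10, 9.5, 9, 1, 0.9, 0.8)), 3L)
  expect_identical(scree_rank(c(10, 9.5, 9, 1, 0.9, 0.8), recursive = TRUE), 3L)
  expect_warning(r <- scree_rank(rep(2, 6)), "constant")
  expect_identical(r, 1L)
  expect_identical(scree_rank(c(10, 9.5, 9, 1, 0.9, 0.8), rank = 50), 50L)
  # two-scale spectrum: recursion descends to the last bend above the floor
  s <- c(12, 11.5, 3.2, 2.9, 1.9, rep(1, 10) - 0.01 * (1:10))
  expect_identical(scree_rank(s), 2L)
  expect_identical(scree_rank(s, recursive = TRUE), 5L)
})

test_that("multi-axis fit at lambda = 0 matches the truncated SVD", {
  set.seed(6)
  X <- matrix(rnorm(50 * 200), 50, 200)
  K <- 5
  fit <- fit_ssvd(X, n_axes = K, lambda = 0)
  sv <- svd(X)
  for (k in seq_len(K)) {
    s <- sign(sum(fit$Z[, k] * sv$u[, k]))
    expect_lt(max(abs(fit$Z[, k] - s * sv$u[, k])), 1e-6)
    expect_lt(max(abs(fit$W[k, ] - s * sv$v[, k])), 1e-6)
  }
  expect_equal(fit$d, sv$d[1:K], tolerance = 1e-8)
  # scores orthonormal; energy conservation under deflation
  expect_lt(max(abs(crossprod(fit$Z) - diag(K))), 1e-6)
  res <- X - fit$Z %*% (fit$d * fit$W)
  expect_equal(sum(X^2), sum(fit$d^2) + sum(res^2), tolerance = 1e-6)
})

test_that("noiseless low-rank data is recovered to machine PVX", {
  set.seed(7)
  Z0 <- matrix(rnorm(40 * 3), 40, 3)
  W0 <- matrix(rnorm(3 * 80), 3, 80)
  X <- Z0 %*% W0
  fit <- fit_ssvd(X, n_axes = 3, lambda = 0)
  expect_gte(fit$pvx, 0.999)
  f1 <- fit_ssvd(X, n_axes = 1, lambda = 0)
  r1 <- rank1_ssvd(X, lambda = 0)
  expect_equal(as.vector(f1$Z), r1$z, tolerance = 1e-10)
  expect_equal(f1$d[1], r1$d, tolerance = 1e-10)
  expect_error(fit_ssvd(X, n_axes = 41), "n_axes")
})

test_that("informative-axis selection honours support and drop_leading", {
  set.seed(8)
  X <- matrix(rnorm(30 * 40), 30, 40)
  dense <- fit_ssvd(X, n_axes = 6, lambda = 0)
  kept <- select_informative_axes(dense, drop_leading = 2)
  expect_setequal(kept, order(dense$d, decreasing = TRUE)[-(1:2)])

  # two planted sparse factors among six requested axes: once the factor
  # signal is exhausted the remaining factors are exactly zero, so only
  # the planted pair carries support and survives selection
  cfg <- synth_config(
    n_samples = 80, n_tissues = 1, block_sizes = c(150), n_factors = 2,
    support_fraction = 0.08, factor_sd = 1, tissue_sd = 0, noise_sd = 0,
    n_clusters = 5, signature_size = 0, seed = 23
  )
  g <- generate_multiomic(cfg)
  X2 <- g$blocks[[1]]$values  # raw: no rescaling of silent features
  fit0 <- fit_ssvd(X2, n_axes = 6, lambda = 0)
  ax0 <- select_informative_axes(fit0)
  expect_setequal(ax0, 1:2)  # axes beyond the planted pair are zero factors

  # with the penalty tuned, sparsity breaks the rotation invariance of the
  # dense SVD: the two leading axes align with the planted factors
  fit <- fit_ssvd(X2, n_axes = 6)
  top2 <- order(fit$d, decreasing = TRUE)[1:2]
  cors <- abs(cor(fit$Z[, top2], g$truth$factor_scores))
  matched <- apply(cors, 1, which.max)
  expect_identical(sort(matched), 1:2)  # distinct factors
  expect_true(all(apply(cors, 1, max) > 0.9))

  # an axis shrunk to nothing by a huge penalty is excluded too
  fit2 <- fit_ssvd(X2, n_axes = 2, lambda = c(0.05, 1e6))
  expect_identical(select_informative_axes(fit2), 1L)
})

test_that("planted sparse support and score space are recovered", {
  g <- generate_multiomic(support_benchmark_config())
  X <- standardized_extended(g)
  fit <- fit_ssvd(X, n_axes = 3)
  truth_support <- colSums(g$truth$support_mask) > 0
  expect_gte(f1_score(fit$feature_support, truth_support), 0.8)
  # per-axis support sizes within a factor of two of the planted size
  planted <- round(0.05 * sum(vapply(g$blocks, function(b) ncol(b$values),
                                     integer(1))))
  supp <- rowSums(fit$W != 0)
  expect_true(all(supp >= planted / 2 & supp <= planted * 2))
  # the fitted score space contains the strongest planted directions:
  # first principal angle essentially zero, all below 15 degrees for the
  # two best-identified factors
  ang <- principal_angles(fit$Z, scale(g$truth$factor_scores, scale = FALSE))
  expect_lt(ang[1], 15)
  expect_lt(ang[2], 15)
  expect_lt(max(ang), 35)
})
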