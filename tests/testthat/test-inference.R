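test_that("standardize centers, scales with n-1, and guards constant columns", {
  X <- cbind(a = c(1, 3), b = c(5, 5))
  s <- standardize(X)
  expect_equal(s$params$mu, c(a = 2, b = 5))
  expect_equal(s$params$sigma, c(a = sqrt(2), b = 1))
  expect_equal(s$Xz[, "a"], c(s1 = -1, s2 = 1) / sqrt(2),
               ignore_attr = TRUE)
  expect_equal(s$Xz[, "b"], c(0, 0), ignore_attr = TRUE)
  # reapplying the stored parameters reproduces Xz
  expect_equal(apply_standardization(X, s$params), s$Xz)
  expect_error(standardize(X[1, , drop = FALSE]), "at least 2")
})

test_that("box_cox matches both branches and is continuous at lambda 0", {
  expect_equal(box_cox(1, 0.5), 0)
  expect_equal(box_cox(8, 0), log(8))
  expect_equal(box_cox(27, 1/3), (3 - 1) * 3)
  expect_equal(box_cox(5, 1e-9), log(5), tolerance = 1e-6)
  expect_error(box_cox(-1, 0.5), "y > 0")
})

test_that("normalize_variance penalizes size and handles the lambda limits", {
  expect_equal(normalize_variance(6, 27, 1/3), 1)
  expect_gt(normalize_variance(10, 30, 1/3), normalize_variance(10, 200, 1/3))
  expect_equal(normalize_variance(10, 5, 1), 10 / 4)
  # size-1 geneset: divisor floored, finite result
  expect_true(is.finite(normalize_variance(3, 1, 0)))
})

test_that("restricted PCA spectrum equals full PCA when g covers all features", {
  Xz <- standardize(rand_expr(12, 6))$Xz
  spec <- geneset_pca_spectrum(Xz, seq_len(6), mode = "full")
  sv <- svd(Xz)
  expect_equal(spec$sqnorm, sv$d[seq_along(spec$sqnorm)]^2, tolerance = 1e-10)
  for (j in seq_along(spec$sqnorm)) {
    expect_equal(abs(sum(spec$vectors[, j] * sv$v[, j])), 1, tolerance = 1e-8)
  }
})

test_that("singleton geneset variance is the column sum of squares over n-1", {
  Xz <- standardize(rand_expr(10, 4))$Xz
  spec <- geneset_pca_spectrum(Xz, 3L)
  expect_equal(spec$values, sum(Xz[, 3]^2) / 9)
  expect_equal(abs(spec$vectors[1, 1]), 1)
})

test_that("rank-1 data yields a single retained component", {
  u <- rnorm(8); v <- rnorm(5)
  Xz <- outer(u, v)
  spec <- geneset_pca_spectrum(Xz, seq_len(5), mode = "full")
  expect_identical(length(spec$sqnorm), 1L)
  expect_equal(spec$sqnorm, sum(Xz^2), tolerance = 1e-10)
})

test_that("order_of_genesets matches a brute-force pooled sort on a toy matrix", {
  Xz <- standardize(rand_expr(4, 7, seed = 3))$Xz
  members <- list(1:3, 3:5, 5:7)
  G <- membership_from_indices(members, 7)
  lam <- 1/3
  # independent oracle: eigen of each restricted covariance, pool, sort
  pool <- do.call(rbind, lapply(seq_along(members), function(i) {
    g <- members[[i]]
    ev <- eigen(crossprod(Xz[, g]), symmetric = TRUE)$values
    ev <- ev[ev > 1e-10 * sum(ev)]
    data.frame(geneset = i, component = seq_along(ev),
               expected = ev / box_cox(length(g), lam))
  }))
  pool <- pool[order(-pool$expected, pool$geneset, pool$component), ]

  ord <- order_of_genesets(Xz, G, a1 = 5, lam = lam)
  expect_identical(nrow(ord), 5L)
  expect_equal(ord$geneset, pool$geneset[1:5])
  expect_equal(ord$component, pool$component[1:5])
  expect_equal(ord$expected, pool$expected[1:5], tolerance = 1e-10)
  # expected values are non-increasing within one ordering call
  expect_true(all(diff(ord$expected) <= 1e-12))

  one <- order_of_genesets(Xz, G, a1 = 1, lam = lam)
  expect_equal(one$geneset, pool$geneset[1])
  expect_equal(one$expected, pool$expected[1], tolerance = 1e-10)
})

test_that("byte-identical genesets tie and break by lower geneset index", {
  Xz <- standardize(rand_expr(4, 7, seed = 5))$Xz
  G <- membership_from_indices(list(2:4, 2:4), 7)
  ord <- order_of_genesets(Xz, G, a1 = 2, lam = 1/3)
  expect_equal(ord$expected[1], ord$expected[2])
  expect_identical(ord$geneset, c(1L, 2L))
  expect_identical(ord$component, c(1L, 1L))
})

test_that("construct_atom returns the restricted leading component, zero-padded", {
  # variance concentrated in one feature inside g -> indicator atom
  Xz <- matrix(0, 10, 5)
  Xz[, 2] <- rnorm(10)
  atom <- construct_atom(Xz, g = c(1L, 2L, 3L))
  expect_equal(atom$coeffs, c(0, 1, 0, 0, 0))
  expect_equal(atom$variance_removed, sum(Xz[, 2]^2))

  # support and norm contract on random input
  Xz <- standardize(rand_expr(8, 10, seed = 2))$Xz
  g <- c(2L, 5L, 9L)
  atom <- construct_atom(Xz, g)
  expect_true(all(atom$coeffs[-g] == 0))
  expect_equal(sum(atom$coeffs^2), 1)

  # g = all features -> leading principal component of Xz
  atom <- construct_atom(Xz, seq_len(10))
  sv <- svd(Xz, nu = 0, nv = 1)
  expect_equal(abs(sum(atom$coeffs * sv$v[, 1])), 1, tolerance = 1e-8)
  expect_equal(atom$variance_removed, sv$d[1]^2, tolerance = 1e-10)

  # fully deflated geneset -> NULL, distinct from success
  expect_null(construct_atom(matrix(0, 4, 3) + standardize(rand_expr(4, 3))$Xz * 0,
                             g = 1:2))
})

test_that("deflate is an idempotent projection with the Frobenius identity", {
  set.seed(11)
  Xz <- standardize(rand_expr(50, 200, seed = 11))$Xz
  d <- rnorm(200); d <- d / sqrt(sum(d^2))
  Y <- deflate(Xz, d)
  expect_lt(max(abs(Y %*% d)), 1e-10)
  expect_equal(sum(Y^2), sum(Xz^2) - sum((Xz %*% d)^2), tolerance = 1e-8)
  expect_equal(deflate(Y, d), Y, tolerance = 1e-10)

  # orthogonal direction leaves the data unchanged
  Xz2 <- cbind(rnorm(10), 0)
  e2 <- c(0, 1)
  expect_equal(deflate(Xz2, e2), Xz2)

  expect_error(deflate(Xz, d * 2), "unit-norm")
})

test_that("one all-covering geneset reduces inference to PCA", {
  Xz <- standardize(rand_expr(30, 40, seed = 8))$Xz
  G <- full_cover_membership(40)
  k <- 5
  inf <- inference_phase(Xz, G, a1 = k, t = 0.9, lam = 1/3)
  sv <- svd(Xz)
  vr <- vapply(inf$atoms, `[[`, numeric(1), "variance_removed")
  expect_equal(vr, sv$d[1:k]^2, tolerance = 1e-6)
  for (j in 1:k) {
    expect_equal(abs(sum(inf$atoms[[j]]$coeffs * sv$v[, j])), 1,
                 tolerance = 1e-6)
  }
})

test_that("t = 0 performs exactly one ordering call", {
  sim <- pasl_simulate(pasl_sim_spec(n = 40, p = 60, n_genesets = 6,
                                     n_active = 4, sizes = c(10, 20),
                                     seed = 4))
  Xz <- standardize(sim$X)$Xz
  inf <- inference_phase(Xz, sim$truth$G, a1 = 6, t = 0, lam = 1/3)
  expect_identical(attr(inf$ledger, "n_order_calls"), 1L)
  expect_identical(attr(inf$ledger, "n_reevaluations"), 0L)
})

test_that("static and dynamic strategies coincide for disjoint genesets", {
  sim <- pasl_simulate(pasl_sim_spec(n = 40, p = 120, n_genesets = 6,
                                     n_active = 6, sizes = c(10, 20),
                                     disjoint = TRUE, seed = 9))
  Xz <- standardize(sim$X)$Xz
  s0 <- inference_phase(Xz, sim$truth$G, a1 = 6, t = 0, lam = 1/3)
  s1 <- inference_phase(Xz, sim$truth$G, a1 = 6, t = 1, lam = 1/3)
  expect_identical(s0$ledger$geneset, s1$ledger$geneset)
  for (j in seq_along(s0$atoms)) {
    expect_equal(s0$atoms[[j]]$coeffs, s1$atoms[[j]]$coeffs, tolerance = 1e-8)
  }
})

test_that("inference invariants: ledger conservation, support, monotone actuals", {
  sim <- pasl_simulate(pasl_sim_spec(n = 50, p = 100, n_genesets = 8,
                                     n_active = 5, sizes = c(15, 30),
                                     seed = 12))
  Xz <- standardize(sim$X)$Xz
  inf <- inference_phase(Xz, sim$truth$G, a1 = 8, t = 1, lam = 1/3)

  vr <- vapply(inf$atoms, `[[`, numeric(1), "variance_removed")
  expect_equal(sum(inf$residual^2) + sum(vr), sum(Xz^2),
               tolerance = 1e-6 * sum(Xz^2))

  for (a in inf$atoms) {
    g <- which(sim$truth$G$matrix[a$geneset_index, ] != 0)
    expect_true(all(a$coeffs[-g] == 0))
    expect_equal(sum(a$coeffs^2), 1, tolerance = 1e-10)
  }

  # with t = 1 each accepted atom is the current best: actuals non-increasing
  expect_true(all(diff(inf$ledger$actual) <= 1e-10))
})

test_that("size penalty: noise-padding a geneset never helps its normalized rank", {
  # statistical property over seeds: doubling the support with pure-noise
  # features lowers (or keeps) the normalized first-component variance
  worse <- 0L
  for (s in 1:20) {
    set.seed(s)
    n <- 40
    signal <- outer(rnorm(n), runif(10, 0.5, 1.5))
    noise <- matrix(rnorm(n * 10, sd = 0.3), n, 10)
    X <- cbind(signal + matrix(rnorm(n * 10, sd = 0.3), n, 10), noise)
    colnames(X) <- paste0("f", 1:20)
    Xz <- standardize(X)$Xz
    v_small <- geneset_pca_spectrum(Xz, 1:10, mode = "first")$sqnorm[1]
    v_big <- geneset_pca_spectrum(Xz, 1:20, mode = "first")$sqnorm[1]
    nv_small <- normalize_variance(v_small, 10, 1/3)
    nv_big <- normalize_variance(v_big, 20, 1/3)
    if (nv_big > nv_small) worse <- worse + 1L
  }
  expect_identical(worse, 0L)
})
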