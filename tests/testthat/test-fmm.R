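pinv_oracle <- function(M) {
  # svd-based pseudoinverse, independent of the implementation path
  sv <- svd(M)
  pos <- sv$d > max(dim(M)) * .Machine$double.eps * max(sv$d)
  sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
    t(sv$u[, pos, drop = FALSE])
}

fake_factorization <- function(G, node_order) {
  structure(list(P = G, S = diag(ncol(G)), G = G, k = ncol(G),
                 node_order = node_order, rse_trace = numeric(),
                 iterations = 0L, ortho_residual = 0),
            class = "fmm_trifactorization")
}

test_that("annotation embedding equals A G for orthonormal G", {
  n <- 24; k <- 6
  G <- nonneg_orthonormal(n, k, seed = 4)
  genes <- sprintf("g%02d", 1:n)
  f <- fake_factorization(G, genes)
  local_seed_test(8, {
    A <- matrix(rbinom(5 * n, 1, 0.3), 5, n,
                dimnames = list(sprintf("t%d", 1:5), genes))
    U <- embed_annotations(f, A)
    expect_lt(max(abs(U - A %*% G)), 1e-10)
    expect_lt(max(abs(U - A %*% pinv_oracle(t(G)))), 1e-10)
  })
})

test_that("single-indicator annotations pick out rows of pinv(G^T)^T", {
  n <- 15; k <- 4
  local_seed_test(5, {
    G <- matrix(stats::runif(n * k), n, k)   # generic, not orthonormal
    genes <- sprintf("g%02d", 1:n)
    f <- fake_factorization(G, genes)
    A <- matrix(0, 3, n, dimnames = list(c("a", "b", "c"), genes))
    picks <- c(2L, 7L, 14L)
    A[cbind(1:3, picks)] <- 1
    U <- embed_annotations(f, A)
    oracle <- pinv_oracle(t(G))[picks, ]   # pinv(G^T) is n x k
    expect_lt(max(abs(U - oracle)), 1e-8)
  })
  expect_error(embed_annotations(fake_factorization(diag(3), letters[1:3]),
                                 matrix(1, 1, 3)), "aligned")
})

test_that("FMM hits the landmark cosine distances and is well-formed", {
  U <- rbind(u1 = c(1, 0), u2 = c(2, 0), u3 = c(0, 3), u4 = c(-1, 0))
  f <- compute_fmm(U)
  expect_equal(f["u1", "u2"], 0)            # same direction
  expect_equal(f["u1", "u3"], 1)            # orthogonal
  expect_equal(f["u1", "u4"], 2)            # opposite
  expect_equal(diag(f), rep(0, 4), ignore_attr = TRUE)
  expect_true(all(f >= 0 & f <= 2))
  expect_identical(f, t(f))
})

test_that("zero annotation vectors are flagged and capped", {
  U <- rbind(a = c(1, 1), b = c(0, 0), c = c(1, 0))
  f <- compute_fmm(U)
  expect_equal(attr(f, "zero_rows"), "b")
  expect_equal(f["b", "a"], 1)
  expect_error(compute_fmm(matrix(0, 3, 2)), "zero")
  expect_error(compute_fmm(rbind(c(0, 0), c(0, 0), c(1, 1)),
                           max_zero_frac = 0.5), "limit")
})

test_that("FMM is invariant to permutations and positive scaling", {
  local_seed_test(6, {
    U <- matrix(stats::rnorm(8 * 3), 8, 3,
                dimnames = list(sprintf("t%d", 1:8), NULL))
    f <- compute_fmm(U)
    perm <- sample(8)
    f_perm <- compute_fmm(U[perm, ])
    expect_equal(f_perm, f[perm, perm], tolerance = 1e-12,
                 ignore_attr = TRUE)
    scales <- stats::runif(8, 0.1, 10)
    f_scaled <- compute_fmm(U * scales)
    expect_equal(f_scaled, f, tolerance = 1e-10, ignore_attr = TRUE)
  })
})

test_that("fmm_rse matches hand-computed quotients", {
  f1 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  f2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(fmm_rse(f1, f1), 0)
  expect_equal(fmm_rse(f1, f2), (2 * 0.5^2) / 2, tolerance = 1e-12)
  expect_equal(fmm_rse(f1, f1 * 0), 1)
  f3 <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_error(fmm_rse(f1, f3), "share no annotations")
})

test_that("fmm_rse aligns on the common annotation subset", {
  local_seed_test(10, {
    ids <- sprintf("t%d", 1:6)
    U <- matrix(stats::rnorm(18), 6, 3, dimnames = list(ids, NULL))
    f_full <- compute_fmm(U)
    f_sub <- compute_fmm(U[c(2, 3, 5), ])
    expect_equal(fmm_rse(f_sub, f_full),
                 fmm_rse(f_sub, f_full[c(2, 3, 5), c(2, 3, 5)]))
  })
})

test_that("dimensionality selection finds the plateau start", {
  # construct FMMs whose consecutive RSEs follow a prescribed profile:
  # base FMM plus shrinking perturbations
  ids <- sprintf("t%d", 1:10)
  base <- local_seed_test(99, {
    U <- matrix(stats::rnorm(30), 10, 3, dimnames = list(ids, NULL))
    compute_fmm(U)
  })
  # scale differences: ||c1*F - c2*F||^2 / ||c1*F||^2 = ((c1-c2)/c1)^2
  fmms <- lapply(c(1, 0.5, 0.3, 0.295, 0.29, 0.285), function(c) base * c)
  names(fmms) <- seq(50, 300, by = 50)
  sel <- optimal_dimensionality(fmms, rel_tol = 0.05)
  # consecutive RSEs: 0.25, 0.16, 2.8e-4, ~2.9e-4, ~3.0e-4 -> plateau at 150
  expect_true(sel$plateau)
  expect_equal(sel$k, 150L)

  flat <- lapply(1:4, function(i) base)
  names(flat) <- c(10, 20, 30, 40)
  # identical FMMs: zero RSE everywhere, plateau from the start
  sel_flat <- optimal_dimensionality(flat)
  expect_equal(sel_flat$k, 10L)

  # relative-scale profile whose consecutive RSEs keep changing sharply
  steep <- lapply(c(1, 0.5, 0.4, 0.38), function(c) base * c)
  names(steep) <- c(10, 20, 30, 40)
  expect_warning(sel_steep <- optimal_dimensionality(steep), "plateau")
  expect_equal(sel_steep$k, 40L)
  expect_false(sel_steep$plateau)
})
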