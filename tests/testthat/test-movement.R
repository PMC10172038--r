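random_fmm <- function(ids, seed) {
  local_seed_test(seed, {
    n <- length(ids)
    m <- matrix(stats::runif(n * n), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(ids, ids)
    m
  })
}

test_that("pairwise movement is an aligned difference and antisymmetric", {
  ids <- sprintf("t%d", 1:8)
  f1 <- random_fmm(ids, 1)
  f2 <- random_fmm(ids, 2)
  mv <- pairwise_movement(f1, f2)
  expect_equal(mv$D, f1 - f2)
  mv_swap <- pairwise_movement(f2, f1)
  expect_equal(mv_swap$D, -mv$D)
  expect_equal(pairwise_movement(f1, f1)$D, f1 * 0)
  # hand-computed 3-annotation toy
  a <- matrix(c(0, .2, .5, .2, 0, .9, .5, .9, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  b <- matrix(c(0, .1, .8, .1, 0, .4, .8, .4, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  expect_equal(pairwise_movement(a, b)$D["x", "y"], 0.1)
  expect_equal(pairwise_movement(a, b)$D["x", "z"], -0.3)
  expect_error(pairwise_movement(a, random_fmm(c("p", "q"), 3)),
               "share no annotations")
})

test_that("percentile rule marks about 5% of pairs on each side", {
  ids <- sprintf("t%03d", 1:120)           # 7140 unordered pairs
  mv <- pairwise_movement(random_fmm(ids, 4), random_fmm(ids, 5))
  sig <- significant_pairs(mv)
  n_pairs <- choose(120, 2)
  expect_equal(nrow(sig$closer) / n_pairs, 0.05, tolerance = 0.01)
  expect_equal(nrow(sig$apart) / n_pairs, 0.05, tolerance = 0.01)
  expect_false(sig$degenerate)
  # closer pairs carry movements at or above the high threshold
  vals <- mv$D[cbind(sig$closer[, "a"], sig$closer[, "b"])]
  expect_true(all(vals >= sig$thresholds[["hi"]]))
})

test_that("identical spaces make the pair thresholds degenerate", {
  ids <- sprintf("t%d", 1:10)
  f <- random_fmm(ids, 6)
  sig <- significant_pairs(pairwise_movement(f, f))
  expect_true(sig$degenerate)
  expect_equal(nrow(sig$closer), choose(10, 2))
  expect_error(significant_pairs(pairwise_movement(random_fmm(ids[1:4], 1),
                                                   random_fmm(ids[1:4], 2))),
               "fewer than 20")
})

test_that("total movement is the rowwise Euclidean norm of D", {
  ids <- c("a", "b", "c")
  f1 <- random_fmm(ids, 7); f2 <- random_fmm(ids, 8)
  mv <- pairwise_movement(f1, f2)
  # 3-4-5 toy: force a known row
  mv$D["a", "b"] <- 3; mv$D["a", "c"] <- 4
  totals <- total_movement(mv)
  expect_equal(unname(totals["a"]), 5)
  # elementwise oracle on a random 5x5
  ids5 <- sprintf("t%d", 1:5)
  mv5 <- pairwise_movement(random_fmm(ids5, 9), random_fmm(ids5, 10))
  t5 <- total_movement(mv5)
  for (i in ids5) {
    oracle <- sqrt(sum(mv5$D[i, setdiff(ids5, i)]^2))
    expect_equal(unname(t5[i]), oracle, tolerance = 1e-12)
  }
  # swapping the spaces leaves totals unchanged
  expect_equal(total_movement(pairwise_movement(f2, f1)),
               total_movement(pairwise_movement(f1, f2)))
})

test_that("shifted/stable classification uses mean +/- 2 population sd", {
  totals <- stats::setNames(c(0, 0, 0, 0, 100), sprintf("t%d", 1:5))
  cls <- classify_shifted_stable(totals)
  # mean 20, population sd 40: threshold exactly 100, inclusive
  expect_equal(cls$mean, 20)
  expect_equal(cls$sd, 40)
  expect_equal(cls$shifted, "t5")
  expect_equal(cls$stable, character())

  flat <- stats::setNames(rep(2, 6), sprintf("t%d", 1:6))
  cls_flat <- classify_shifted_stable(flat)
  expect_true(cls_flat$degenerate)
  expect_equal(cls_flat$shifted, character())
  expect_equal(cls_flat$stable, character())
})

test_that("Gaussian totals put about 2.3% of annotations in each tail", {
  local_seed_test(14, {
    totals <- stats::setNames(stats::rnorm(10000), sprintf("t%d", 1:10000))
    cls <- classify_shifted_stable(totals)
    expect_equal(length(cls$shifted) / 10000, 0.023, tolerance = 0.25)
    expect_equal(length(cls$stable) / 10000, 0.023, tolerance = 0.25)
  })
})

test_that("significant pair sets are invariant to annotation permutation", {
  ids <- sprintf("t%02d", 1:30)
  f1 <- random_fmm(ids, 15); f2 <- random_fmm(ids, 16)
  sig <- significant_pairs(pairwise_movement(f1, f2))
  local_seed_test(17, {
    perm <- sample(ids)
    sig_p <- significant_pairs(pairwise_movement(f1[perm, perm],
                                                 f2[perm, perm]))
    canon <- function(m) {
      paste(pmin(m[, "a"], m[, "b"]), pmax(m[, "a"], m[, "b"]))
    }
    expect_setequal(canon(sig_p$closer), canon(sig$closer))
    expect_setequal(canon(sig_p$apart), canon(sig$apart))
  })
})

test_that("gene scores follow the 95th-percentile construction", {
  # two fabricated spaces sharing genes; scores computed then thresholded
  n <- 100; k <- 4
  genes <- sprintf("g%03d", 1:n)
  mk_space <- function(seed) {
    local_seed_test(seed, {
      G <- abs(matrix(stats::rnorm(n * k), n, k))
      f <- structure(list(P = G, S = diag(k), G = G, k = k,
                          node_order = genes, rse_trace = numeric(),
                          iterations = 0L, ortho_residual = 0),
                     class = "fmm_trifactorization")
      A <- matrix(rbinom(6 * n, 1, 0.2), 6, n,
                  dimnames = list(sprintf("t%d", 1:6), genes))
      list(f = f, U = embed_annotations(f, A))
    })
  }
  s1 <- mk_space(18); s2 <- mk_space(19)
  gm <- gene_movement_scores(s1$f, s2$f, s1$U, s2$U,
                             shifted = c("t1", "t2"))
  expect_equal(length(gm$predicted), 5L)   # 5% of 100 genes, inclusive >=
  expect_true(all(gm$scores[gm$predicted] >= gm$threshold))
  # identical spaces: all scores zero, degenerate, nothing predicted
  gm0 <- gene_movement_scores(s1$f, s1$f, s1$U, s1$U, shifted = "t1")
  expect_true(gm0$degenerate)
  expect_equal(gm0$predicted, character())
  expect_error(gene_movement_scores(s1$f, s2$f, s1$U, s2$U,
                                    shifted = character()), "non-empty")
})
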