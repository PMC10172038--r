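#' Relative square error of a tri-factorization
#'
#' RSE = ||X - P S G^T||_F^2 / ||X||_F^2. Zero if and only if the
#' factorization reproduces X exactly; equal to 1 for the trivial all-zero
#' factorization.
#'
#' @param X the factorized matrix.
#' @param f an `fmm_trifactorization` (or any list with P, S, G).
#' @return non-negative scalar.
#' @export
rse <- function(X, f) {
  denom <- sum(X^2)
  if (denom == 0) stop("RSE undefined: ||X||_F = 0")
  Xhat <- f$P %*% f$S %*% t(f$G)
  sum((X - Xhat)^2) / denom
}

new_trifactorization <- function(P, S, G, k, node_order,
                                 rse_trace = numeric(), iterations = 0L) {
  structure(list(P = P, S = S, G = G, k = as.integer(k),
                 node_order = node_order,
                 rse_trace = rse_trace,
                 iterations = as.integer(iterations),
                 ortho_residual = norm(crossprod(G) - diag(k), "F")),
            class = "fmm_trifactorization")
}

#' @export
print.fmm_trifactorization <- function(x, ...) {
  cat(sprintf(
    "fmm_trifactorization: n = %d, k = %d, %d iterations, final RSE = %s\n",
    nrow(x$P), x$k, x$iterations,
    if (length(x$rse_trace)) format(utils::tail(x$rse_trace, 1L), digits = 4)
    else "NA"))
  cat(sprintf("  ||G'G - I||_F = %.3g\n", x$ortho_residual))
  invisible(x)
}

#' Deterministic SVD-based initialization for NMTF
#'
#' Initial factors from the truncated rank-k singular value decomposition
#' X ~ U_k S_k V_k^T: P0 = |U_k|, S0 = diag(S_k), G0 = |V_k| (elementwise
#' absolute values to enforce non-negativity). The initialization involves
#' no randomness, which makes the whole solver deterministic and typically
#' shortens convergence.
#'
#' @param X symmetric non-negative matrix (e.g. a PPMI matrix) with node ids
#'   as dimnames.
#' @param k embedding dimensionality, 1 <= k <= nrow(X).
#' @return an `fmm_trifactorization` holding the initial factors.
#' @export
svd_initialize <- function(X, k) {
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("`k` must satisfy 1 <= k <= nrow(X)")
  sv <- svd(X, nu = k, nv = k)
  P0 <- abs(sv$u[, seq_len(k), drop = FALSE])
  G0 <- abs(sv$v[, seq_len(k), drop = FALSE])
  S0 <- diag(sv$d[seq_len(k)], k, k)
  node_order <- rownames(X)
  if (!is.null(node_order)) rownames(P0) <- rownames(G0) <- node_order
  new_trifactorization(P0, S0, G0, k, node_order)
}

#' Orthonormality-constrained non-negative matrix tri-factorization
#'
#' Decomposes a symmetric non-negative matrix X as X ~ P S G^T with all
#' factors non-negative and G constrained towards column-orthonormality
#' (G^T G = I), by minimising ||X - P S G^T||_F^2 with multiplicative update
#' rules from the KKT conditions of the constrained objective:
#'
#'   P <- P * (X G S^T)   / (P S G^T G S^T)
#'   S <- S * (P^T X G)   / (P^T P S G^T G)
#'   G <- G * sqrt( (X^T P S) / (G G^T X^T P S) )
#'
#' (elementwise product and quotient; denominators stabilised with a small
#' epsilon). The square root in the G rule is the damping that comes with
#' the orthogonality-constrained KKT derivation; without it the G update
#' overshoots and the objective oscillates. Rows of P S are the gene embedding vectors; columns of G are
#' the basis of the embedding space. Starting factors come from
#' [svd_initialize()], so the solver is fully deterministic. Iteration stops
#' when the relative RSE improvement drops below `tol`, when the RSE would
#' increase (the last improving iterate is kept), or at `max_iter`.
#'
#' @param X symmetric non-negative matrix with node ids as dimnames.
#' @param k embedding dimensionality.
#' @param max_iter maximum number of update sweeps (default 500).
#' @param tol relative RSE improvement below which iteration stops
#'   (default 1e-6).
#' @param eps stabilising constant added to update denominators.
#' @return an `fmm_trifactorization` with the fitted factors, the RSE trace
#'   (one value per accepted sweep, starting from the initialization), the
#'   number of sweeps used, and the orthonormality residual ||G^T G - I||_F.
#' @export
nmtf_decompose <- function(X, k, max_iter = 500L, tol = 1e-6, eps = 1e-12) {
  if (any(X < 0)) stop("X must be non-negative")
  if (max(abs(X - t(X))) > 1e-8) stop("X must be symmetric")
  f <- svd_initialize(X, k)
  P <- f$P; S <- f$S; G <- f$G
  trace <- rse(X, f)
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    XG <- X %*% G
    GtG <- crossprod(G)
    P_new <- P * (XG %*% t(S)) / (P %*% S %*% GtG %*% t(S) + eps)
    PtX <- crossprod(P_new, X)
    PtP <- crossprod(P_new)
    S_new <- S * (PtX %*% G) / (PtP %*% S %*% GtG + eps)
    XtPS <- crossprod(X, P_new %*% S_new)
    G_new <- G * sqrt(XtPS / (G %*% crossprod(G, XtPS) + eps))
    if (!all(is.finite(P_new)) || !all(is.finite(S_new)) ||
        !all(is.finite(G_new))) {
      stop("non-finite values in multiplicative update at iteration ", it)
    }
    r <- rse(X, list(P = P_new, S = S_new, G = G_new))
    last <- trace[length(trace)]
    if (r > last) break                      # keep the last improving iterate
    P <- P_new; S <- S_new; G <- G_new
    trace <- c(trace, r)
    iterations <- it
    if (last > 0 && (last - r) / last < tol) break
  }
  out <- new_trifactorization(P, S, G, k, f$node_order, trace, iterations)
  out
}

#' Gene embedding vectors of a tri-factorization
#'
#' The embedding vector of gene i is row i of P S.
#'
#' @param f an `fmm_trifactorization`.
#' @return n x k matrix with gene ids as rownames.
#' @export
gene_embeddings <- function(f) {
  E <- f$P %*% f$S
  rownames(E) <- f$node_order
  E
}
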