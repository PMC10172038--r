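#' Cosine distances between the rows of two matrices
#'
#' `1 - cos(x_i, y_j)` for every row pair. Rows with zero norm get distance 1
#' to everything (maximally uninformative) rather than NaN.
#'
#' @param Xr,Yr numeric matrices with the same number of columns.
#' @return `nrow(Xr)` x `nrow(Yr)` matrix of cosine distances in [0, 2].
#' @export
cosine_distances <- function(Xr, Yr) {
  nx <- sqrt(rowSums(Xr^2))
  ny <- sqrt(rowSums(Yr^2))
  sim <- tcrossprod(Xr, Yr)
  denom <- outer(nx, ny)
  zero <- denom == 0
  denom[zero] <- 1
  d <- 1 - sim / denom
  d[zero] <- 1
  # clip tiny numerical excursions outside [0, 2]
  d[d < 0] <- 0
  d[d > 2] <- 2
  rownames(d) <- rownames(Xr)
  colnames(d) <- rownames(Yr)
  d
}

#' Embed annotations into a gene embedding space
#'
#' Given the basis factor G of a gene embedding space and the binary
#' annotation-by-gene matrix A (columns aligned to the space's node order),
#' the annotation embedding vectors U solve A ~ U G^T, i.e.
#' U = A pinv(G^T) with pinv the Moore-Penrose pseudoinverse. When G is
#' exactly column-orthonormal this reduces to U = A G. Rows of U may be
#' negative: annotations are projected, not factorized.
#'
#' @param f an `fmm_trifactorization`.
#' @param A binary annotation-by-gene matrix from [annotation_matrix()],
#'   with colnames equal to `f$node_order`.
#' @return annotations x k matrix U with annotation ids as rownames.
#' @export
embed_annotations <- function(f, A) {
  if (is.null(colnames(A)) || is.null(f$node_order) ||
      !identical(colnames(A), f$node_order)) {
    stop("gene columns of A are not aligned to the factorization node order")
  }
  U <- A %*% MASS::ginv(t(f$G))
  rownames(U) <- rownames(A)
  U
}

#' Functional Mapping Matrix
#'
#' The FMM of an embedding space is the symmetric matrix of pairwise cosine
#' distances between the annotation embedding vectors: FMM[i, j] is the
#' cosine distance between u_i and u_j, with a zero diagonal and values in
#' [0, 2]. Because cosine distance is scale-normalised, FMMs of different
#' spaces (different conditions, different dimensionalities) are directly
#' comparable without further normalisation.
#'
#' @param U annotations x k embedding matrix from [embed_annotations()].
#' @param max_zero_frac maximum tolerated fraction of all-zero annotation
#'   vectors (default 0.5); zero vectors get distance 1 to everything and are
#'   recorded in the `zero_rows` attribute.
#' @return symmetric matrix with annotation ids as dimnames and attribute
#'   `zero_rows`.
#' @export
compute_fmm <- function(U, max_zero_frac = 0.5) {
  norms <- sqrt(rowSums(U^2))
  zero <- norms == 0
  if (all(zero)) stop("all annotation embedding vectors are zero")
  if (mean(zero) > max_zero_frac) {
    stop(sprintf("%.0f%% of annotation vectors are zero (limit %.0f%%)",
                 100 * mean(zero), 100 * max_zero_frac))
  }
  d <- cosine_distances(U, U)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  attr(d, "zero_rows") <- rownames(U)[zero]
  d
}

#' Align two FMMs on their common annotation set
#'
#' @param f1,f2 FMM matrices with annotation dimnames.
#' @return list with both matrices restricted to the shared annotations, in
#'   the order they appear in `f1`.
#' @export
align_fmms <- function(f1, f2) {
  common <- intersect(rownames(f1), rownames(f2))
  if (length(common) == 0L) stop("FMMs share no annotations")
  list(f1 = f1[common, common, drop = FALSE],
       f2 = f2[common, common, drop = FALSE],
       annotations = common)
}

#' Relative square error between two FMMs
#'
#' ||F1 - F2||_F^2 / ||F1||_F^2 over the common annotation set: the measure
#' of how much the functional organisation captured by `f1` differs from
#' that captured by `f2`.
#'
#' @param f1,f2 FMM matrices with annotation dimnames.
#' @return non-negative scalar.
#' @export
fmm_rse <- function(f1, f2) {
  al <- align_fmms(f1, f2)
  denom <- sum(al$f1^2)
  if (denom == 0) stop("reference FMM has zero Frobenius norm")
  sum((al$f1 - al$f2)^2) / denom
}

#' Optimal embedding dimensionality from an FMM sweep
#'
#' Given FMMs of the same network computed at an increasing grid of
#' dimensionalities, computes the RSE between the FMMs at consecutive grid
#' points and finds where that sequence plateaus, i.e. stops decreasing: the
#' smallest dimensionality from which every subsequent consecutive RSE
#' changes by relative amount < `rel_tol`. Beyond that point additional
#' dimensions no longer change the functional organisation of the space.
#'
#' @param fmms_by_dim named list of FMM matrices; names are the
#'   dimensionalities (coercible to integer), in increasing order.
#' @param rel_tol relative-change threshold defining the plateau
#'   (default 0.05).
#' @return list with `k` (chosen dimensionality), `dims`, `rse` (consecutive
#'   RSEs, attached to the lower dimension of each pair), `rel_change`, and
#'   `plateau` (FALSE, with a warning, when no plateau exists and the largest
#'   dimensionality is returned).
#' @export
optimal_dimensionality <- function(fmms_by_dim, rel_tol = 0.05) {
  dims <- as.integer(names(fmms_by_dim))
  if (length(dims) < 3L) stop("need FMMs at >= 3 dimensionalities")
  if (is.unsorted(dims, strictly = TRUE)) {
    stop("dimensionalities must be strictly increasing")
  }
  m <- length(dims)
  rses <- vapply(seq_len(m - 1L), function(j) {
    fmm_rse(fmms_by_dim[[j]], fmms_by_dim[[j + 1L]])
  }, 0)
  rel_change <- abs(diff(rses)) / pmax(rses[-length(rses)], .Machine$double.eps)
  flat <- rel_change < rel_tol
  # smallest index from which all later consecutive RSEs are flat
  start <- NA_integer_
  for (j in seq_along(flat)) {
    if (all(flat[j:length(flat)])) { start <- j; break }
  }
  if (is.na(start)) {
    warning("no RSE plateau at rel_tol = ", rel_tol,
            "; returning the largest dimensionality")
    return(list(k = dims[m], dims = dims, rse = rses,
                rel_change = rel_change, plateau = FALSE))
  }
  list(k = dims[start], dims = dims, rse = rses,
       rel_change = rel_change, plateau = TRUE)
}
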