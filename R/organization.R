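#' Cluster annotations on their FMM distances
#'
#' Partitions the annotations with the k-medoids (PAM) algorithm applied
#' directly to the precomputed cosine-distance matrix. With `k = "auto"` the
#' number of clusters follows the usual rule of thumb k = round(sqrt(n/2)).
#' PAM's BUILD initialisation is deterministic, so the assignment depends
#' only on the distance matrix; the seed is recorded for provenance.
#'
#' @param fmm an FMM matrix (symmetric cosine distances, annotation
#'   dimnames).
#' @param k integer number of clusters (>= 2) or `"auto"`.
#' @param seed integer recorded alongside the assignment.
#' @return named integer vector of cluster labels, one per annotation, with
#'   attributes `k` and `seed`.
#' @export
cluster_annotations <- function(fmm, k = "auto", seed = 1L) {
  n <- nrow(fmm)
  if (identical(k, "auto")) k <- max(2L, round(sqrt(n / 2)))
  k <- as.integer(k)
  if (k > n) stop("`k` cannot exceed the number of annotations")
  if (k < 1L) stop("`k` must be >= 1")
  if (k == n) {
    cl <- stats::setNames(seq_len(n), rownames(fmm))
  } else {
    fit <- local_seed(seed, cluster::pam(stats::as.dist(fmm), k = k))
    cl <- stats::setNames(as.integer(fit$clustering), rownames(fmm))
  }
  attr(cl, "k") <- k
  attr(cl, "seed") <- as.integer(seed)
  cl
}

upper_pairs <- function(n) {
  # index pairs i < j as two integer vectors
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2:n)
  cbind(i = i, j = j)
}

#' Functional-organization report of an embedding space
#'
#' Quantifies whether semantically similar annotations lie close together in
#' an embedding space. Annotations are clustered on their FMM distances with
#' k-medoids; the report gives the mean Lin similarity of within-cluster
#' annotation pairs (`intra`), of between-cluster pairs (`inter`), their
#' ratio (`fold`), a one-sided Mann-Whitney U p-value for within > between
#' (`mw_p`), and the Pearson correlation between cosine distance and Lin
#' similarity over all pairs (`pearson_r`; negative when closeness in space
#' tracks semantic similarity). A functionally organised space has
#' fold > 1, small `mw_p` and negative `pearson_r`; a randomised space sits
#' near fold = 1.
#'
#' @param fmm an FMM matrix.
#' @param ic an `fmm_ic_table`.
#' @param ont an `fmm_ontology`.
#' @param k clusters for [cluster_annotations()] (default `"auto"`).
#' @param seed seed recorded with the clustering.
#' @return an `fmm_organization_report` list: `k_clusters`, `clustering`,
#'   `intra`, `inter`, `fold`, `mw_p`, `pearson_r`, `degenerate` (TRUE when
#'   the Lin values carry no variance so that `pearson_r` is undefined and
#'   reported as 0).
#' @export
organization_report <- function(fmm, ic, ont, k = "auto", seed = 1L) {
  ann <- rownames(fmm)
  cl <- cluster_annotations(fmm, k = k, seed = seed)
  L <- lin_similarity_matrix(ann, ic, ont)
  pr <- upper_pairs(length(ann))
  lin_vals <- L[pr]
  dist_vals <- fmm[pr]
  same <- cl[pr[, "i"]] == cl[pr[, "j"]]
  if (!any(same)) stop("no within-cluster annotation pairs (all singletons)")
  intra <- mean(lin_vals[same])
  inter <- mean(lin_vals[!same])
  fold <- if (inter == 0) {
    if (intra == 0) 1 else Inf   # identical Lin everywhere -> no preference
  } else intra / inter
  degenerate <- stats::sd(lin_vals) == 0 || stats::sd(dist_vals) == 0
  mw_p <- if (stats::sd(lin_vals) == 0) 1 else
    stats::wilcox.test(lin_vals[same], lin_vals[!same],
                       alternative = "greater", exact = FALSE)$p.value
  pearson_r <- if (degenerate) 0 else stats::cor(dist_vals, lin_vals)
  structure(list(k_clusters = attr(cl, "k"), clustering = cl,
                 intra = intra, inter = inter, fold = fold,
                 mw_p = mw_p, pearson_r = pearson_r,
                 degenerate = degenerate, seed = attr(cl, "seed")),
            class = "fmm_organization_report")
}

#' @export
print.fmm_organization_report <- function(x, ...) {
  cat(sprintf(paste0(
    "fmm_organization_report: %d clusters\n",
    "  intra = %.3f, inter = %.3f, fold = %.2f\n",
    "  Mann-Whitney p = %.3g, Pearson r(distance, Lin) = %.3f%s\n"),
    x$k_clusters, x$intra, x$inter, x$fold, x$mw_p, x$pearson_r,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Are annotations embedded close to the genes they annotate?
#'
#' For every annotation, the cosine distances from its embedding vector to
#' the vectors of the genes it annotates and to the vectors of all other
#' genes are pooled into two samples; a one-sided Mann-Whitney U test asks
#' whether annotated genes are closer. A small p-value confirms that genes
#' and annotations are consistently placed in the same space.
#'
#' @param f an `fmm_trifactorization` (gene vectors are rows of P S).
#' @param U annotation embedding matrix from [embed_annotations()].
#' @param A binary annotation-by-gene matrix aligned to both.
#' @return one-sided Mann-Whitney U p-value (alternative: annotated genes
#'   closer).
#' @export
gene_function_proximity_test <- function(f, U, A) {
  if (!identical(colnames(A), f$node_order)) {
    stop("A's gene columns are not aligned to the factorization")
  }
  if (!identical(rownames(A), rownames(U))) {
    stop("A's annotation rows are not aligned to the embedding")
  }
  E <- gene_embeddings(f)
  D <- cosine_distances(U, E)
  has_genes <- rowSums(A) > 0
  if (!any(has_genes)) stop("no annotation annotates any embedded gene")
  D <- D[has_genes, , drop = FALSE]
  A <- A[has_genes, , drop = FALSE]
  annotated <- D[A == 1]
  others <- D[A == 0]
  if (length(others) == 0L) stop("every gene is annotated by every annotation")
  stats::wilcox.test(annotated, others, alternative = "less",
                     exact = FALSE)$p.value
}
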