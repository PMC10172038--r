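#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `k` marked items in a sample of `n` from a population of `N`
#' containing `K` marked items. The standard one-sided enrichment p-value.
#'
#' @param k observed successes in the selection.
#' @param K successes in the background.
#' @param n selection size.
#' @param N background size.
#' @return p-value in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (N < K || N < n || k < 0 || k > min(K, n)) {
    stop("inconsistent hypergeometric counts: k=", k, " K=", K,
         " n=", n, " N=", N)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Lower-tail hypergeometric probability
#'
#' P(X <= k): the depletion counterpart of [hypergeom_upper_tail()].
#'
#' @inheritParams hypergeom_upper_tail
#' @return p-value in (0, 1].
#' @export
hypergeom_lower_tail <- function(k, K, n, N) {
  if (N < K || N < n || k < 0 || k > min(K, n)) {
    stop("inconsistent hypergeometric counts: k=", k, " K=", K,
         " n=", n, " N=", N)
  }
  stats::phyper(k, K, N - K, n, lower.tail = TRUE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, preserving the input order.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals <= 0 | pvals > 1 | !is.finite(pvals))) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Annotation enrichment of a gene selection
#'
#' One hypergeometric test per annotation: is the annotation over-represented
#' in `selection` relative to `background`? Used both to define
#' condition-related annotations from a seed gene set (e.g. known oncogenes)
#' and, through [category_enrichment()], to test whether shifted annotations
#' are enriched in condition-related ones.
#'
#' @param selection character vector of selected gene ids (subset of
#'   `background`).
#' @param background character vector of background gene ids.
#' @param table an `fmm_annotation_table`.
#' @param alpha significance level on the BH-adjusted p-value (default 0.05).
#' @return data frame with one row per annotation having at least one
#'   background gene: `term`, `k`, `K`, `n`, `N`, `p`, `p_adj`,
#'   `significant`; ordered by `p`.
#' @export
enriched_annotations <- function(selection, background, table, alpha = 0.05) {
  selection <- unique(as.character(selection))
  background <- unique(as.character(background))
  if (!all(selection %in% background)) {
    stop("`selection` must be a subset of `background`")
  }
  pairs <- table$pairs[table$pairs$gene %in% background, , drop = FALSE]
  if (nrow(pairs) == 0L) stop("no annotation has a background gene")
  terms <- sort(unique(pairs$term))
  N <- length(background)
  n <- length(selection)
  res <- do.call(rbind, lapply(terms, function(t) {
    g <- pairs$gene[pairs$term == t]
    K <- length(g)
    k <- length(intersect(g, selection))
    data.frame(term = t, k = k, K = K, n = n, N = N,
               p = hypergeom_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- bh_adjust(res$p)
  res$significant <- res$p_adj <= alpha
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Enrichment of an item set in a binary category
#'
#' Hypergeometric test of whether `selection` (e.g. the shifted annotations)
#' contains more members of `category` (e.g. condition-related annotations)
#' than expected from `universe` (e.g. all embedded annotations). Also
#' reports the depletion (lower-tail) p-value.
#'
#' @param selection character vector, subset of `universe`.
#' @param category character vector of category members.
#' @param universe character vector of all items.
#' @return one-row data frame: `k`, `K`, `n`, `N`, `p_enrich`, `p_deplete`.
#' @export
category_enrichment <- function(selection, category, universe) {
  selection <- unique(as.character(selection))
  universe <- unique(as.character(universe))
  category <- intersect(unique(as.character(category)), universe)
  if (!all(selection %in% universe)) {
    stop("`selection` must be a subset of `universe`")
  }
  k <- length(intersect(selection, category))
  data.frame(k = k, K = length(category), n = length(selection),
             N = length(universe),
             p_enrich = hypergeom_upper_tail(k, length(category),
                                             length(selection),
                                             length(universe)),
             p_deplete = hypergeom_lower_tail(k, length(category),
                                              length(selection),
                                              length(universe)))
}
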