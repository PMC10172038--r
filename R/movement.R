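#' Pairwise movement between two condition-specific FMMs
#'
#' The movement matrix D = FMM_control - FMM_case over the common annotation
#' set. Sign convention: D[i, j] > 0 means the embedding vectors of
#' annotations i and j are closer in the case space than in the control
#' space; D[i, j] < 0 means they moved apart in the case space. Swapping
#' the arguments negates D.
#'
#' @param fmm_control FMM of the control (reference) space.
#' @param fmm_case FMM of the case (e.g. cancer) space.
#' @return an `fmm_movement` list: `D` (annotations x annotations),
#'   `annotations`.
#' @export
pairwise_movement <- function(fmm_control, fmm_case) {
  al <- align_fmms(fmm_control, fmm_case)
  structure(list(D = al$f1 - al$f2, annotations = al$annotations),
            class = "fmm_movement")
}

#' @export
print.fmm_movement <- function(x, ...) {
  cat(sprintf("fmm_movement: %d annotations, mean |D| = %.4f\n",
              length(x$annotations), mean(abs(x$D[upper.tri(x$D)]))))
  invisible(x)
}

#' Annotation pairs moving significantly closer or apart
#'
#' Applies the percentile rule to the distribution of movements over all
#' unordered off-diagonal annotation pairs: pairs with movement at or above
#' the `hi`-th percentile moved significantly closer in the case space;
#' pairs at or below the `lo`-th percentile moved significantly apart
#' (positive movement = closer in case, see [pairwise_movement()]).
#' Percentiles use linear interpolation (quantile type 7) and inclusive
#' comparison.
#'
#' @param movement an `fmm_movement`.
#' @param lo,hi percentile bounds (defaults 5 and 95).
#' @return list with `closer` and `apart` (two-column matrices of annotation
#'   id pairs), `thresholds`, and `degenerate` (TRUE when the two thresholds
#'   coincide, e.g. identical input spaces).
#' @export
significant_pairs <- function(movement, lo = 5, hi = 95) {
  D <- movement$D
  n <- nrow(D)
  pr <- upper_pairs(n)
  vals <- D[pr]
  if (length(vals) < 20L) {
    stop("fewer than 20 annotation pairs: percentile thresholds meaningless")
  }
  thr <- stats::quantile(vals, probs = c(lo, hi) / 100, type = 7, names = FALSE)
  ann <- movement$annotations
  closer <- pr[vals >= thr[2L], , drop = FALSE]
  apart <- pr[vals <= thr[1L], , drop = FALSE]
  as_id_pairs <- function(m) {
    cbind(a = ann[m[, "i"]], b = ann[m[, "j"]])
  }
  list(closer = as_id_pairs(closer), apart = as_id_pairs(apart),
       thresholds = stats::setNames(thr, c("lo", "hi")),
       n_pairs = length(vals),
       degenerate = thr[1L] == thr[2L])
}

#' Total movement of each annotation
#'
#' The Euclidean norm of an annotation's row of the movement matrix D
#' (diagonal excluded): how much the annotation's distances to all other
#' annotations changed between the two spaces.
#'
#' @param movement an `fmm_movement`.
#' @return named numeric vector of total movements.
#' @export
total_movement <- function(movement) {
  D <- movement$D
  diag(D) <- 0
  stats::setNames(sqrt(rowSums(D^2)), movement$annotations)
}

#' Shifted and stable annotations from the total-movement distribution
#'
#' An annotation is *shifted* when its total movement lies at least two
#' standard deviations above the mean of the total-movement distribution,
#' and *stable* when it lies at least two standard deviations below. The
#' standard deviation is the population form (the totals are the whole
#' distribution, not a sample).
#'
#' @param totals named numeric vector from [total_movement()].
#' @param n_sd number of standard deviations defining the tails (default 2).
#' @return list with `shifted` and `stable` (annotation id vectors), `mean`,
#'   `sd`, `thresholds`, and `degenerate` (TRUE when sd = 0, in which case
#'   both sets are empty).
#' @export
classify_shifted_stable <- function(totals, n_sd = 2) {
  if (length(totals) < 3L) stop("need at least 3 annotations")
  mu <- mean(totals)
  sigma <- sqrt(mean((totals - mu)^2))   # population sd
  if (sigma == 0) {
    return(list(shifted = character(), stable = character(),
                mean = mu, sd = sigma,
                thresholds = c(lo = mu, hi = mu), degenerate = TRUE))
  }
  hi <- mu + n_sd * sigma
  lo <- mu - n_sd * sigma
  list(shifted = names(totals)[totals >= hi],
       stable = names(totals)[totals <= lo],
       mean = mu, sd = sigma,
       thresholds = c(lo = lo, hi = hi), degenerate = FALSE)
}

#' Movement analysis of two condition-specific FMMs
#'
#' Convenience wrapper running [pairwise_movement()], [significant_pairs()],
#' [total_movement()] and [classify_shifted_stable()] in one call.
#'
#' @param fmm_control,fmm_case FMM matrices.
#' @param lo,hi percentiles for [significant_pairs()].
#' @param n_sd tail width for [classify_shifted_stable()].
#' @return an `fmm_movement_report` list combining all components.
#' @export
movement_report <- function(fmm_control, fmm_case, lo = 5, hi = 95, n_sd = 2) {
  mv <- pairwise_movement(fmm_control, fmm_case)
  sig <- significant_pairs(mv, lo = lo, hi = hi)
  totals <- total_movement(mv)
  cls <- classify_shifted_stable(totals, n_sd = n_sd)
  structure(c(list(movement = mv, totals = totals), sig["closer"],
              sig["apart"], list(pair_thresholds = sig$thresholds,
                                 pair_degenerate = sig$degenerate),
              cls),
            class = "fmm_movement_report")
}

#' @export
print.fmm_movement_report <- function(x, ...) {
  cat(sprintf(paste0(
    "fmm_movement_report: %d annotations\n",
    "  closer pairs: %d, apart pairs: %d%s\n",
    "  total movement: mean %.4f, sd %.4f\n",
    "  shifted: %d, stable: %d%s\n"),
    length(x$totals), nrow(x$closer), nrow(x$apart),
    if (x$pair_degenerate) " [degenerate]" else "",
    x$mean, x$sd, length(x$shifted), length(x$stable),
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Gene scores from movement relative to shifted annotations
#'
#' For each gene present in both spaces and each shifted annotation, the
#' movement of the gene-annotation pair is the absolute change of their
#' cosine distance between the control and the case space (gene vectors are
#' rows of P S, annotation vectors rows of U, in each space). A gene's score
#' is its maximum movement magnitude over the shifted annotations; genes at
#' or above the 95th percentile of the score distribution are predicted as
#' condition-related.
#'
#' @param f_control,f_case `fmm_trifactorization`s of the two spaces.
#' @param U_control,U_case annotation embeddings of the two spaces.
#' @param shifted character vector of shifted annotation ids (non-empty),
#'   present in both embeddings.
#' @param percentile prediction cutoff percentile (default 95).
#' @return an `fmm_gene_movement` list: `scores` (named, decreasing),
#'   `threshold`, `predicted` (gene ids), `degenerate` (TRUE when all scores
#'   are equal, in which case no gene is predicted).
#' @export
gene_movement_scores <- function(f_control, f_case, U_control, U_case,
                                 shifted, percentile = 95) {
  if (length(shifted) == 0L) stop("`shifted` must be non-empty")
  genes <- intersect(f_control$node_order, f_case$node_order)
  if (length(genes) == 0L) stop("the two spaces share no genes")
  miss <- setdiff(shifted, intersect(rownames(U_control), rownames(U_case)))
  if (length(miss) > 0L) {
    stop("shifted annotation(s) missing from an embedding: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  Ec <- gene_embeddings(f_control)[genes, , drop = FALSE]
  Ex <- gene_embeddings(f_case)[genes, , drop = FALSE]
  Dc <- cosine_distances(Ec, U_control[shifted, , drop = FALSE])
  Dx <- cosine_distances(Ex, U_case[shifted, , drop = FALSE])
  M <- abs(Dc - Dx)
  scores <- apply(M, 1L, max)
  thr <- stats::quantile(scores, percentile / 100, type = 7, names = FALSE)
  degenerate <- stats::sd(scores) == 0
  predicted <- if (degenerate) character() else names(scores)[scores >= thr]
  structure(list(scores = sort(scores, decreasing = TRUE), threshold = thr,
                 predicted = predicted, degenerate = degenerate),
            class = "fmm_gene_movement")
}

#' @export
print.fmm_gene_movement <- function(x, ...) {
  cat(sprintf(
    "fmm_gene_movement: %d genes scored, %d predicted (threshold %.4f)%s\n",
    length(x$scores), length(x$predicted), x$threshold,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
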