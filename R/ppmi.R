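#' Closed-form PPMI matrix of a network
#'
#' Computes the positive pointwise mutual information (PPMI) representation
#' of an undirected network using the closed-form random-walk co-occurrence
#' matrix: with adjacency matrix A, degree matrix D, transition matrix
#' P = D^-1 A and volume vol = sum of degrees,
#'
#'   M = vol / (negatives * window) * sum_{r=1..window} P^r D^-1,
#'
#' and PPMI = max(log M, 0) elementwise (natural log; entries with M = 0 map
#' to 0). Each entry of M measures how often two nodes co-occur within
#' `window` steps of a random walk, normalised by the walk's stationary
#' visiting rates, so the PPMI captures high-order proximity between genes
#' rather than only direct interaction.
#'
#' @param network an [fmm_network()]; every node must have degree >= 1.
#' @param window random-walk context window T (number of diffusion steps
#'   summed; default 10).
#' @param negatives negative-sampling constant b in the closed form
#'   (default 1).
#' @return symmetric non-negative dense matrix with dimnames following the
#'   network's node order; attributes `window` and `negatives` record the
#'   parameters.
#' @export
ppmi_matrix <- function(network, window = 10L, negatives = 1L) {
  if (length(network$nodes) < 2L) stop("network must have at least 2 nodes")
  if (window < 1L) stop("`window` must be >= 1")
  if (negatives < 1L) stop("`negatives` must be >= 1")
  deg <- network_degrees(network)
  if (any(deg == 0L)) {
    stop("network has isolated node(s): ",
         paste(utils::head(names(deg)[deg == 0L], 5L), collapse = ", "))
  }
  A <- adjacency_matrix(network)
  inv_deg <- 1 / deg
  P <- A * inv_deg               # row-scaled: D^-1 A
  vol <- sum(deg)
  Pr <- diag(nrow(A))
  S <- matrix(0, nrow(A), ncol(A))
  for (r in seq_len(window)) {
    Pr <- Pr %*% P
    S <- S + Pr
  }
  M <- (vol / (negatives * window)) * sweep(S, 2L, inv_deg, `*`)
  X <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(A))
  pos <- M > 0
  X[pos] <- pmax(log(M[pos]), 0)
  # exact symmetry can drift at machine precision through the matrix powers
  X <- (X + t(X)) / 2
  attr(X, "window") <- as.integer(window)
  attr(X, "negatives") <- as.integer(negatives)
  X
}
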