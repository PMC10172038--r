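#' Construct a network object
#'
#' A `fmm_network` is an undirected simple graph over gene identifiers with a
#' stable, lexicographic node ordering. The ordering fixes the row order of
#' every matrix derived from the network (adjacency, PPMI, factor matrices),
#' so that all downstream objects are aligned by construction.
#'
#' @param edges two-column character matrix or data frame of edge endpoints.
#' @param nodes optional character vector of node ids; defaults to the sorted
#'   set of edge endpoints. May include ids with no edges (isolated nodes);
#'   downstream matrix operations reject those.
#' @return an object of class `fmm_network` with elements `nodes` (sorted
#'   character vector) and `edges` (m x 2 character matrix, each row sorted,
#'   rows ordered lexicographically, no self-loops, no duplicates).
#' @export
fmm_network <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (ncol(edges) < 2L) stop("edges must have two columns")
  edges <- cbind(as.character(edges[, 1L]), as.character(edges[, 2L]))
  keep <- edges[, 1L] != edges[, 2L]
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) > 0L) {
    swap <- edges[, 1L] > edges[, 2L]
    edges[swap, ] <- edges[swap, c(2L, 1L)]
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  endpoint_set <- sort(unique(as.vector(edges)))
  if (is.null(nodes)) {
    nodes <- endpoint_set
  } else {
    nodes <- sort(unique(as.character(nodes)))
    if (!all(endpoint_set %in% nodes)) {
      stop("every edge endpoint must appear in `nodes`")
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "fmm_network")
}

#' @export
print.fmm_network <- function(x, ...) {
  cat(sprintf("fmm_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of nodes and edges
#' @param network an `fmm_network`.
#' @return integer count.
#' @export
n_nodes <- function(network) length(network$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(network) nrow(network$edges)

#' Node degrees
#' @param network an `fmm_network`.
#' @return named integer vector in node order.
#' @export
network_degrees <- function(network) {
  d <- stats::setNames(integer(length(network$nodes)), network$nodes)
  if (nrow(network$edges) > 0L) {
    tab <- table(factor(as.vector(network$edges), levels = network$nodes))
    d[] <- as.integer(tab)
  }
  d
}

#' Adjacency matrix of a network
#' @param network an `fmm_network`.
#' @return symmetric 0/1 matrix with dimnames following the node order.
#' @export
adjacency_matrix <- function(network) {
  n <- length(network$nodes)
  A <- matrix(0, n, n, dimnames = list(network$nodes, network$nodes))
  if (nrow(network$edges) > 0L) {
    i <- match(network$edges[, 1L], network$nodes)
    j <- match(network$edges[, 2L], network$nodes)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  A
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    as.data.frame(network$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE))
}

from_igraph <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  fmm_network(el)
}

#' Read an undirected edge list
#'
#' Parses a delimited edge list into an [fmm_network()]. Lines starting with
#' `#` and blank lines are ignored; extra columns (e.g. scores) are dropped.
#' Self-loops are discarded and duplicate edges (in either orientation)
#' collapse to one. Nodes are the endpoints of the retained edges, sorted
#' lexicographically: a gene whose only interaction is a self-loop is
#' therefore absent from the result.
#'
#' @param path path to the edge-list file.
#' @param delimiter field separator, default tab; any whitespace run when
#'   `delimiter = ""`.
#' @return an `fmm_network`.
#' @export
read_edge_list <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(fmm_network(matrix(character(), ncol = 2L)))
  split_one <- function(line) {
    if (nzchar(delimiter)) strsplit(line, delimiter, fixed = TRUE)[[1L]]
    else strsplit(trimws(line), "\\s+")[[1L]]
  }
  fields <- lapply(lines[idx], split_one)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("edge-list parse error at line %d of %s: fewer than 2 fields",
                 idx[bad[1L]], path))
  }
  el <- t(vapply(fields, function(f) trimws(f[1:2]), character(2L)))
  fmm_network(el)
}

#' Write an edge list
#'
#' Inverse of [read_edge_list()]: the written file, re-read, reproduces the
#' same edge set and node ordering.
#'
#' @param network an `fmm_network`.
#' @param path output path.
#' @param delimiter field separator (default tab).
#' @export
write_edge_list <- function(network, path, delimiter = "\t") {
  lines <- apply(network$edges, 1L, paste, collapse = delimiter)
  writeLines(lines, path)
  invisible(path)
}

#' Build a tissue-specific subnetwork
#'
#' Restricts a generic interaction network to the genes expressed in a given
#' tissue: the induced subgraph on the expressed genes, with genes left
#' without any interaction after induction removed (a tissue network keeps
#' only genes that are expressed and retain at least one interaction).
#'
#' @param generic an `fmm_network` (the generic interactome).
#' @param expressed character vector of expressed gene ids.
#' @return an `fmm_network` on the expressed, still-connected genes.
#' @export
build_tissue_network <- function(generic, expressed) {
  expressed <- unique(as.character(expressed))
  if (length(expressed) == 0L) stop("`expressed` must be non-empty")
  common <- intersect(generic$nodes, expressed)
  if (length(common) == 0L) {
    stop("no expressed gene is present in the generic network")
  }
  keep <- generic$edges[, 1L] %in% common & generic$edges[, 2L] %in% common
  edges <- generic$edges[keep, , drop = FALSE]
  if (nrow(edges) == 0L) {
    stop("tissue induction left no interactions (all induced genes isolated)")
  }
  fmm_network(edges)
}

#' Read a gene-annotation table
#'
#' Reads annotation assignments as either a two-column TSV
#' (`annotation id<TAB>gene id`) or a GAF 2.x file. For GAF input only rows
#' whose aspect column is `P` (Biological Process) are retained; the gene id
#' is taken from column 3 (object symbol) and the term id from column 5.
#'
#' @param path input path.
#' @param dialect `"two-column-tsv"` or `"gaf"`.
#' @return an `fmm_annotation_table`: list with `pairs` (data frame with
#'   columns `term`, `gene`), `terms` and `genes` (sorted id vectors).
#' @export
read_annotations <- function(path, dialect = c("two-column-tsv", "gaf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(!|#|$)", lines)]
  if (dialect == "two-column-tsv") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ok <- vapply(fields, length, 1L) >= 2L
    if (!all(ok)) {
      stop("annotation TSV parse error: line with fewer than 2 fields")
    }
    term <- vapply(fields, `[`, "", 1L)
    gene <- vapply(fields, `[`, "", 2L)
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ok <- vapply(fields, length, 1L) >= 9L
    fields <- fields[ok]
    aspect <- vapply(fields, `[`, "", 9L)
    fields <- fields[aspect == "P"]
    term <- vapply(fields, `[`, "", 5L)
    gene <- vapply(fields, `[`, "", 3L)
  }
  annotation_table(term, gene)
}

#' Construct an annotation table from id vectors
#'
#' @param term character vector of annotation ids.
#' @param gene character vector of gene ids, same length.
#' @return an `fmm_annotation_table` (duplicated pairs removed).
#' @export
annotation_table <- function(term, gene) {
  stopifnot(length(term) == length(gene))
  pairs <- unique(data.frame(term = as.character(term),
                             gene = as.character(gene),
                             stringsAsFactors = FALSE))
  if (nrow(pairs) == 0L) stop("annotation table has zero retained pairs")
  pairs <- pairs[order(pairs$term, pairs$gene), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 terms = sort(unique(pairs$term)),
                 genes = sort(unique(pairs$gene))),
            class = "fmm_annotation_table")
}

#' @export
print.fmm_annotation_table <- function(x, ...) {
  cat(sprintf("fmm_annotation_table: %d pairs, %d terms, %d genes\n",
              nrow(x$pairs), length(x$terms), length(x$genes)))
  invisible(x)
}

#' Write an annotation table as two-column TSV
#' @param table an `fmm_annotation_table`.
#' @param path output path.
#' @export
write_annotations <- function(table, path) {
  utils::write.table(table$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Binary annotation-by-gene incidence matrix
#'
#' Builds the relation matrix A between annotations and genes: `A[a, g]` is 1
#' if annotation `a` annotates gene `g` and 0 otherwise. Columns follow the
#' supplied gene ordering (typically a network's node order); annotations
#' annotating fewer than `min_genes` of those genes are dropped.
#'
#' @param table an `fmm_annotation_table`.
#' @param gene_order character vector fixing the column order.
#' @param min_genes minimum number of in-order genes an annotation must
#'   annotate to be retained (default 1).
#' @return binary matrix with annotation ids as rownames and `gene_order` as
#'   colnames.
#' @export
annotation_matrix <- function(table, gene_order, min_genes = 1L) {
  gene_order <- as.character(gene_order)
  if (length(gene_order) == 0L) stop("`gene_order` must be non-empty")
  if (anyDuplicated(gene_order)) stop("`gene_order` has duplicated ids")
  pairs <- table$pairs[table$pairs$gene %in% gene_order, , drop = FALSE]
  counts <- table(pairs$term)
  keep_terms <- sort(names(counts)[counts >= min_genes])
  if (length(keep_terms) == 0L) {
    stop("no annotation annotates at least `min_genes` genes in `gene_order`")
  }
  A <- matrix(0, length(keep_terms), length(gene_order),
              dimnames = list(keep_terms, gene_order))
  pairs <- pairs[pairs$term %in% keep_terms, , drop = FALSE]
  A[cbind(match(pairs$term, keep_terms), match(pairs$gene, gene_order))] <- 1
  A
}
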