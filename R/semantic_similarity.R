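#' Construct an ontology object
#'
#' A directed acyclic graph of terms linked by `is_a` edges, each term
#' carrying a namespace. Only `is_a` is modelled; other relation types
#' (part_of, regulates, ...) are not traversed.
#'
#' @param terms character vector of term ids.
#' @param parents named list: for each term, the character vector of its
#'   direct `is_a` parents (possibly empty). Parents must be terms.
#' @param namespace named character vector giving each term's namespace.
#' @return an `fmm_ontology` with precomputed ancestor closures (each term's
#'   ancestor set includes the term itself) and the namespace roots.
#' @export
ontology <- function(terms, parents, namespace) {
  terms <- unique(as.character(terms))
  parents <- parents[terms]
  names(parents) <- terms
  parents <- lapply(parents, function(p) {
    if (is.null(p)) character() else intersect(as.character(p), terms)
  })
  namespace <- namespace[terms]
  # ancestor closure by memoised DFS; cycle detection on the way
  anc <- vector("list", length(terms))
  names(anc) <- terms
  state <- stats::setNames(integer(length(terms)), terms)  # 0 new, 1 open, 2 done
  visit <- function(t) {
    if (state[[t]] == 2L) return(anc[[t]])
    if (state[[t]] == 1L) stop("ontology is_a graph contains a cycle at ", t)
    state[[t]] <<- 1L
    up <- unique(unlist(lapply(parents[[t]], visit), use.names = FALSE))
    anc[[t]] <<- unique(c(t, up))
    state[[t]] <<- 2L
    anc[[t]]
  }
  for (t in terms) visit(t)
  roots <- terms[vapply(parents, length, 1L) == 0L]
  structure(list(terms = terms, parents = parents, namespace = namespace,
                 ancestors = anc, roots = roots),
            class = "fmm_ontology")
}

#' @export
print.fmm_ontology <- function(x, ...) {
  cat(sprintf("fmm_ontology: %d terms, %d root(s), namespaces: %s\n",
              length(x$terms), length(x$roots),
              paste(unique(x$namespace), collapse = ", ")))
  invisible(x)
}

#' All ancestors of a term
#' @param ont an `fmm_ontology`.
#' @param term a term id.
#' @param include_self include the term itself (default TRUE).
#' @return character vector of term ids.
#' @export
term_ancestors <- function(ont, term, include_self = TRUE) {
  a <- ont$ancestors[[term]]
  if (is.null(a)) stop("unknown term: ", term)
  if (include_self) a else setdiff(a, term)
}

#' Read an OBO flat file
#'
#' Minimal reader for OBO 1.2/1.4 `[Term]` stanzas. Only `id`, `namespace`,
#' `is_a` and `is_obsolete` are consumed; obsolete terms are dropped, and
#' `is_a` references to terms not defined in the file are ignored.
#'
#' @param path path to the .obo file.
#' @return an `fmm_ontology`.
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path)
  ids <- character(); ns <- character(); obs <- logical()
  parents <- list()
  cur_id <- NA_character_; cur_ns <- NA_character_
  cur_par <- character(); cur_obs <- FALSE
  in_term <- FALSE
  default_ns <- NA_character_
  flush <- function() {
    if (in_term && !is.na(cur_id)) {
      ids[length(ids) + 1L] <<- cur_id
      ns[length(ns) + 1L] <<- cur_ns
      obs[length(obs) + 1L] <<- cur_obs
      parents[[cur_id]] <<- cur_par
    }
  }
  for (line in lines) {
    line <- sub("\\s*!.*$", "", trimws(line))
    if (line == "") next
    if (grepl("^\\[", line)) {
      flush()
      in_term <- identical(line, "[Term]")
      cur_id <- NA_character_; cur_ns <- NA_character_
      cur_par <- character(); cur_obs <- FALSE
      next
    }
    kv <- regmatches(line, regexec("^([a-zA-Z_-]+):\\s*(.*)$", line))[[1L]]
    if (length(kv) != 3L) next
    key <- kv[2L]; val <- trimws(kv[3L])
    if (!in_term) {
      if (key == "default-namespace") default_ns <- val
      next
    }
    if (key == "id") cur_id <- val
    else if (key == "namespace") cur_ns <- val
    else if (key == "is_a") cur_par <- c(cur_par, sub("\\s.*$", "", val))
    else if (key == "is_obsolete" && tolower(val) == "true") cur_obs <- TRUE
  }
  flush()
  if (length(ids) == 0L) stop("no [Term] stanzas found in ", path)
  keep <- !obs
  ids <- ids[keep]; ns <- ns[keep]; parents <- parents[ids]
  ns[is.na(ns)] <- if (!is.na(default_ns)) default_ns else "default"
  ontology(ids, parents, stats::setNames(ns, ids))
}

#' Write an ontology as an OBO flat file
#' @param ont an `fmm_ontology`.
#' @param path output path.
#' @export
write_obo <- function(ont, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in ont$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t),
                 paste0("namespace: ", ont$namespace[[t]]),
                 paste0("is_a: ", ont$parents[[t]])), con)
  }
  invisible(path)
}

#' Corpus-based information content of ontology terms
#'
#' Propagates each gene's annotations to all `is_a` ancestors (the true-path
#' rule), then sets p(t) = (number of genes annotated to t or any of its
#' descendants) / (number of genes annotated within t's namespace root) and
#' ic(t) = -ln p(t). The namespace root always has ic 0; ic grows with term
#' specificity. Annotation terms absent from the ontology are dropped with a
#' warning; terms annotating no gene after propagation carry no finite ic
#' and are omitted from the table.
#'
#' @param ont an `fmm_ontology`.
#' @param table an `fmm_annotation_table` (the IC corpus).
#' @return an `fmm_ic_table`: list with `ic` (named numeric), `gene_counts`
#'   (propagated genes per term) and `corpus_size` (total propagated
#'   gene-term assignments).
#' @export
information_content <- function(ont, table) {
  pairs <- table$pairs
  known <- pairs$term %in% ont$terms
  if (!any(known)) stop("no annotation term overlaps the ontology")
  if (!all(known)) {
    warning(sum(!known), " annotation pair(s) use terms absent from the ",
            "ontology and were dropped")
    pairs <- pairs[known, , drop = FALSE]
  }
  # propagate each (term, gene) pair to all ancestors of the term
  anc_sizes <- lengths(ont$ancestors[pairs$term])
  prop <- data.frame(
    term = unlist(ont$ancestors[pairs$term], use.names = FALSE),
    gene = rep(pairs$gene, anc_sizes),
    stringsAsFactors = FALSE)
  prop <- unique(prop)
  counts <- table(prop$term)
  gene_counts <- stats::setNames(as.integer(counts), names(counts))
  # per-namespace totals: genes reaching the namespace root
  ns_of <- ont$namespace
  root_count <- function(t) {
    ns_roots <- intersect(ont$roots, names(ns_of)[ns_of == ns_of[[t]]])
    tot <- sum(gene_counts[intersect(ns_roots, names(gene_counts))])
    if (is.na(tot) || tot == 0L) NA_integer_ else tot
  }
  ic <- vapply(names(gene_counts), function(t) {
    tot <- root_count(t)
    if (is.na(tot)) return(NA_real_)
    -log(gene_counts[[t]] / tot)
  }, 0)
  ic <- ic[!is.na(ic)]
  structure(list(ic = ic, gene_counts = gene_counts,
                 corpus_size = nrow(prop)),
            class = "fmm_ic_table")
}

#' Lin semantic similarity between two ontology terms
#'
#' 2 ic(MICA) / (ic(t1) + ic(t2)), where MICA is the common `is_a` ancestor
#' with maximal information content. Zero when the terms share no ancestor
#' (e.g. different namespaces) or when the only shared ancestor is an
#' uninformative root (both numerator and denominator zero).
#'
#' @param t1,t2 term ids.
#' @param ic an `fmm_ic_table`.
#' @param ont an `fmm_ontology`.
#' @return similarity in [0, 1].
#' @export
lin_similarity <- function(t1, t2, ic, ont) {
  for (t in c(t1, t2)) {
    if (is.na(ic$ic[t])) stop("term without information content: ", t)
  }
  common <- intersect(term_ancestors(ont, t1), term_ancestors(ont, t2))
  common <- common[!is.na(ic$ic[common])]
  if (length(common) == 0L) return(0)
  mica_ic <- max(ic$ic[common])
  denom <- ic$ic[[t1]] + ic$ic[[t2]]
  if (denom == 0) return(0)
  unname(2 * mica_ic / denom)
}

#' Pairwise Lin similarity matrix over a term set
#'
#' @param terms character vector of term ids.
#' @param ic an `fmm_ic_table`.
#' @param ont an `fmm_ontology`.
#' @return symmetric matrix of Lin similarities (diagonal = self-similarity).
#' @export
lin_similarity_matrix <- function(terms, ic, ont) {
  n <- length(terms)
  L <- matrix(0, n, n, dimnames = list(terms, terms))
  for (i in seq_len(n)) {
    for (j in i:n) {
      L[i, j] <- L[j, i] <- lin_similarity(terms[i], terms[j], ic, ont)
    }
  }
  L
}

#' Mean pairwise Lin similarity between two term sets
#'
#' Mean of `lin_similarity` over the cross product of the two sets. When the
#' two sets are identical, self-pairs (t, t) are excluded so the mean
#' reflects between-term similarity only.
#'
#' @param setA,setB character vectors of term ids (non-empty).
#' @param ic an `fmm_ic_table`.
#' @param ont an `fmm_ontology`.
#' @return scalar mean similarity.
#' @export
mean_pairwise_lin <- function(setA, setB, ic, ont) {
  if (length(setA) == 0L || length(setB) == 0L) stop("term sets must be non-empty")
  same <- setequal(setA, setB)
  vals <- c()
  for (a in setA) {
    for (b in setB) {
      if (same && a == b) next
      vals <- c(vals, lin_similarity(a, b, ic, ont))
    }
  }
  if (length(vals) == 0L) stop("no term pairs to average over")
  mean(vals)
}
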