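#' Build a full embedding space from a network and annotations
#'
#' Runs the whole per-condition pipeline: PPMI representation of the
#' network, orthonormality-constrained NMTF at dimensionality `k`,
#' annotation embedding, and the FMM of the resulting space.
#'
#' @param network an `fmm_network`.
#' @param table an `fmm_annotation_table`.
#' @param k embedding dimensionality.
#' @param window,negatives PPMI parameters (see [ppmi_matrix()]).
#' @param min_genes annotation-size filter (see [annotation_matrix()]).
#' @param max_iter,tol NMTF stopping parameters (see [nmtf_decompose()]).
#' @return an `fmm_space` list: `network`, `X` (PPMI), `f`
#'   (tri-factorization), `A` (annotation matrix), `U` (annotation
#'   embedding), `fmm`.
#' @export
embedding_space <- function(network, table, k, window = 10L, negatives = 1L,
                            min_genes = 1L, max_iter = 500L, tol = 1e-6) {
  X <- ppmi_matrix(network, window = window, negatives = negatives)
  f <- nmtf_decompose(X, k, max_iter = max_iter, tol = tol)
  A <- annotation_matrix(table, network$nodes, min_genes = min_genes)
  U <- embed_annotations(f, A)
  structure(list(network = network, X = X, f = f, A = A, U = U,
                 fmm = compute_fmm(U)),
            class = "fmm_space")
}

#' @export
print.fmm_space <- function(x, ...) {
  cat(sprintf("fmm_space: %d genes, %d annotations, k = %d\n",
              length(x$network$nodes), nrow(x$A), x$f$k))
  invisible(x)
}

#' Compare two condition-specific embedding spaces
#'
#' Computes the movement report between the control and case FMMs and, when
#' any annotation is classified as shifted, the gene movement scores and
#' predictions.
#'
#' @param space_control,space_case `fmm_space` objects from
#'   [embedding_space()].
#' @param lo,hi,n_sd,percentile see [movement_report()] and
#'   [gene_movement_scores()].
#' @return list with `movement` (an `fmm_movement_report`) and `genes` (an
#'   `fmm_gene_movement`, or NULL when no annotation shifted).
#' @export
compare_spaces <- function(space_control, space_case, lo = 5, hi = 95,
                           n_sd = 2, percentile = 95) {
  mv <- movement_report(space_control$fmm, space_case$fmm,
                        lo = lo, hi = hi, n_sd = n_sd)
  genes <- NULL
  if (length(mv$shifted) > 0L) {
    genes <- gene_movement_scores(space_control$f, space_case$f,
                                  space_control$U, space_case$U,
                                  mv$shifted, percentile = percentile)
  }
  list(movement = mv, genes = genes)
}

default_config <- function() {
  list(window = 10L, negatives = 1L, k = 15L,
       k_grid = c(10L, 20L, 30L, 40L), min_genes = 1L,
       max_iter = 500L, tol = 1e-6, rel_tol = 0.05,
       lo = 5, hi = 95, n_sd = 2, percentile = 95, alpha = 0.05,
       seed = 1L, out = ".")
}

#' Load a pipeline configuration
#'
#' Merges, in increasing precedence: package defaults, a YAML config file,
#' and explicit overrides (e.g. command-line flags). Unknown fields are
#' rejected with the offending name.
#'
#' @param path optional YAML file.
#' @param overrides named list of fields overriding the file.
#' @return configuration list for [run_pipeline()].
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), c(names(cfg), "control", "case", "network",
                                  "expressed", "annotations", "obo",
                                  "selection", "background", "dialect"))
    if (length(bad) > 0L) {
      stop("unknown config field(s): ", paste(bad, collapse = ", "))
    }
    cfg[names(user)] <- user
  }
  cfg[names(overrides)] <- overrides
  cfg
}

#' Run one pipeline stage from a configuration
#'
#' Command-style interface over the package: each subcommand reads the
#' documented text formats, runs the corresponding stage, and writes TSV
#' artifacts plus a JSON manifest (parameters, traces, thresholds, set
#' sizes) into the output directory. Subcommands: `simulate`,
#' `build-network`, `ppmi`, `embed`, `fmm`, `choose-dim`, `organization`,
#' `movement`, `predict-genes`, `enrich`.
#'
#' @param subcommand one of the stage names above.
#' @param config configuration list as from a YAML file; recognised fields
#'   include input paths (`network`, `expressed`, `annotations`, `obo`,
#'   `control`, `case`, `selection`, `background`), numeric parameters
#'   (`window`, `negatives`, `k`, `k_grid`, `min_genes`, `max_iter`, `tol`,
#'   `rel_tol`, `lo`, `hi`, `n_sd`, `percentile`, `alpha`, `seed`) and the
#'   output directory `out`. Unspecified fields take package defaults.
#' @return list of written file paths, invisibly.
#' @export
run_pipeline <- function(subcommand, config = list()) {
  cfg <- default_config()
  cfg[names(config)] <- config
  out <- cfg$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(path) { written <<- c(written, path); path }
  manifest <- function(x, name) {
    emit(write_json_manifest(c(x, list(config = cfg)),
                             file.path(out, name)))
  }
  need <- function(field) {
    if (is.null(cfg[[field]])) stop("config field required: ", field)
    cfg[[field]]
  }
  space_from_cfg <- function(net_path) {
    net <- read_edge_list(net_path)
    tab <- read_annotations(need("annotations"),
                            dialect = cfg$dialect %||% "two-column-tsv")
    embedding_space(net, tab, k = cfg$k, window = cfg$window,
                    negatives = cfg$negatives, min_genes = cfg$min_genes,
                    max_iter = cfg$max_iter, tol = cfg$tol)
  }
  switch(
    subcommand,
    "simulate" = {
      sc <- synthetic_scenario(seed = cfg$seed)
      write_scenario(sc, out)
      emit(file.path(out, c("control.edgelist.tsv", "case.edgelist.tsv",
                            "annotations.tsv", "ontology.obo", "truth.json")))
    },
    "build-network" = {
      net <- read_edge_list(need("network"))
      expressed <- readLines(need("expressed"))
      expressed <- expressed[nzchar(trimws(expressed))]
      tissue <- build_tissue_network(net, expressed)
      emit(write_edge_list(tissue, file.path(out, "tissue.edgelist.tsv")))
      manifest(list(nodes = tissue$nodes, n_edges = nrow(tissue$edges)),
               "tissue.manifest.json")
    },
    "ppmi" = {
      net <- read_edge_list(need("network"))
      X <- ppmi_matrix(net, cfg$window, cfg$negatives)
      emit(write_matrix_tsv(X, file.path(out, "ppmi.tsv")))
      manifest(list(nodes = net$nodes, window = cfg$window,
                    negatives = cfg$negatives), "ppmi.manifest.json")
    },
    "embed" = {
      net <- read_edge_list(need("network"))
      X <- ppmi_matrix(net, cfg$window, cfg$negatives)
      f <- nmtf_decompose(X, cfg$k, cfg$max_iter, cfg$tol)
      emit(write_matrix_tsv(f$P, file.path(out, "P.tsv")))
      S <- f$S; dimnames(S) <- list(seq_len(f$k), seq_len(f$k))
      emit(write_matrix_tsv(S, file.path(out, "S.tsv")))
      emit(write_matrix_tsv(f$G, file.path(out, "G.tsv")))
      manifest(list(k = f$k, iterations = f$iterations,
                    final_rse = utils::tail(f$rse_trace, 1L),
                    rse_trace = f$rse_trace,
                    ortho_residual = f$ortho_residual),
               "embed.manifest.json")
    },
    "fmm" = {
      sp <- space_from_cfg(need("network"))
      emit(write_matrix_tsv(sp$U, file.path(out, "U.tsv")))
      emit(write_matrix_tsv(sp$fmm, file.path(out, "fmm.tsv")))
      manifest(list(annotations = rownames(sp$fmm), k = sp$f$k,
                    zero_rows = attr(sp$fmm, "zero_rows")),
               "fmm.manifest.json")
    },
    "choose-dim" = {
      net <- read_edge_list(need("network"))
      tab <- read_annotations(need("annotations"),
                              dialect = cfg$dialect %||% "two-column-tsv")
      fmms <- lapply(cfg$k_grid, function(k) {
        embedding_space(net, tab, k = k, window = cfg$window,
                        negatives = cfg$negatives,
                        min_genes = cfg$min_genes,
                        max_iter = cfg$max_iter, tol = cfg$tol)$fmm
      })
      names(fmms) <- cfg$k_grid
      sel <- optimal_dimensionality(fmms, rel_tol = cfg$rel_tol)
      manifest(sel[c("k", "dims", "rse", "rel_change", "plateau")],
               "dimensionality.json")
    },
    "organization" = {
      sp <- space_from_cfg(need("network"))
      ont <- read_obo(need("obo"))
      tab <- read_annotations(need("annotations"),
                              dialect = cfg$dialect %||% "two-column-tsv")
      ic <- information_content(ont, tab)
      rep <- organization_report(sp$fmm, ic, ont, seed = cfg$seed)
      members <- data.frame(annotation = names(rep$clustering),
                            cluster = as.integer(rep$clustering))
      emit(file.path(out, "clusters.tsv"))
      utils::write.table(members, file.path(out, "clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest(rep[c("k_clusters", "intra", "inter", "fold", "mw_p",
                     "pearson_r", "degenerate", "seed")],
               "organization.json")
    },
    "movement" = {
      sp_control <- space_from_cfg(need("control"))
      sp_case <- space_from_cfg(need("case"))
      cmp <- compare_spaces(sp_control, sp_case, lo = cfg$lo, hi = cfg$hi,
                            n_sd = cfg$n_sd, percentile = cfg$percentile)
      mv <- cmp$movement
      totals <- data.frame(annotation = names(mv$totals),
                           total_movement = unname(mv$totals))
      totals <- totals[order(-totals$total_movement), ]
      emit(file.path(out, "total_movement.tsv"))
      utils::write.table(totals, file.path(out, "total_movement.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest(list(n_annotations = length(mv$totals),
                    n_closer = nrow(mv$closer), n_apart = nrow(mv$apart),
                    pair_thresholds = as.list(mv$pair_thresholds),
                    pair_degenerate = mv$pair_degenerate,
                    mean = mv$mean, sd = mv$sd,
                    shifted = mv$shifted, stable = mv$stable,
                    degenerate = mv$degenerate),
               "movement.json")
    },
    "predict-genes" = {
      sp_control <- space_from_cfg(need("control"))
      sp_case <- space_from_cfg(need("case"))
      cmp <- compare_spaces(sp_control, sp_case, lo = cfg$lo, hi = cfg$hi,
                            n_sd = cfg$n_sd, percentile = cfg$percentile)
      if (is.null(cmp$genes)) {
        manifest(list(shifted = character(), predicted = character(),
                      degenerate = TRUE), "genes.json")
      } else {
        gm <- cmp$genes
        ranked <- data.frame(gene = names(gm$scores),
                             score = unname(gm$scores))
        emit(file.path(out, "gene_scores.tsv"))
        utils::write.table(ranked, file.path(out, "gene_scores.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        manifest(list(shifted = cmp$movement$shifted,
                      threshold = gm$threshold, predicted = gm$predicted,
                      degenerate = gm$degenerate), "genes.json")
      }
    },
    "enrich" = {
      tab <- read_annotations(need("annotations"),
                              dialect = cfg$dialect %||% "two-column-tsv")
      selection <- readLines(need("selection"))
      background <- readLines(need("background"))
      res <- enriched_annotations(selection[nzchar(selection)],
                                  background[nzchar(background)],
                                  tab, alpha = cfg$alpha)
      emit(file.path(out, "enrichment.tsv"))
      utils::write.table(res, file.path(out, "enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      manifest(list(n_tested = nrow(res),
                    n_significant = sum(res$significant),
                    alpha = cfg$alpha), "enrichment.json")
    },
    stop("unknown subcommand: ", subcommand)
  )
  invisible(written)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
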