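#' Planted-partition (stochastic block model) network
#'
#' Generates a modular undirected network: genes are split into modules of
#' equal size; each within-module gene pair is connected with probability
#' `p_in` and each between-module pair with probability `p_out` (< `p_in`).
#' Connectivity is guaranteed by adding a spanning cycle over the modules
#' (one edge from each module to the next) and by attaching any gene left
#' isolated to a random member of its own module, so every gene has at
#' least one interaction.
#'
#' @param n_modules number of modules.
#' @param module_size genes per module.
#' @param p_in within-module edge probability.
#' @param p_out between-module edge probability (0 <= p_out < p_in <= 1).
#' @param seed integer seed; the generator is fully reproducible.
#' @return list with `network` (an [fmm_network()]) and `modules` (named
#'   character vector gene -> module id `"M1"`, `"M2"`, ...).
#' @export
planted_partition_network <- function(n_modules = 12L, module_size = 20L,
                                      p_in = 0.4, p_out = 0.015, seed = 1L) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("require 0 <= p_out < p_in <= 1")
  }
  n <- n_modules * module_size
  genes <- sprintf("g%04d", seq_len(n))
  modules <- stats::setNames(
    rep(sprintf("M%d", seq_len(n_modules)), each = module_size), genes)
  local_seed(seed, {
    pr <- upper_pairs(n)
    same <- modules[pr[, "i"]] == modules[pr[, "j"]]
    p <- ifelse(same, p_in, p_out)
    keep <- stats::runif(nrow(pr)) < p
    edges <- cbind(genes[pr[keep, "i"]], genes[pr[keep, "j"]])
    # spanning cycle over modules for connectivity
    firsts <- genes[seq(1L, n, by = module_size)]
    cyc <- cbind(firsts, firsts[c(2:n_modules, 1L)])
    edges <- rbind(edges, cyc)
    net <- fmm_network(edges)
    isolated <- setdiff(genes, net$nodes)
    if (length(isolated) > 0L) {
      fix <- t(vapply(isolated, function(g) {
        mates <- setdiff(genes[modules == modules[[g]]], g)
        c(g, sample(mates, 1L))
      }, character(2L)))
      net <- fmm_network(rbind(net$edges, fix))
    }
    list(network = net, modules = modules)
  })
}

#' Module-aligned annotations with a toy ontology
#'
#' Creates `terms_per_module` annotation terms per module; each term
#' annotates a fraction `coverage` of its module's genes plus a fraction
#' `leak` of the remaining genes (annotation noise, drawn uniformly from
#' all genes outside the term's own gene set so that no pair of terms is
#' privileged in how it can share noise genes). Sibling terms of the same
#' module draw their genes without replacement from a shuffled pool of the
#' module's genes, so their gene sets are disjoint whenever
#' `coverage * terms_per_module <= 1`: any closeness of sibling terms in an
#' embedding space then reflects the network's module structure, not mere
#' gene-set overlap (annotations with heavily overlapping gene sets would
#' sit close in any space, including a randomized one). The accompanying toy
#' ontology has a single root, one mid-level parent per module, and the
#' terms as leaves, so terms of the same module are semantically closer
#' (share a more informative ancestor) than terms of different modules.
#'
#' @param modules named character vector gene -> module id, as produced by
#'   [planted_partition_network()].
#' @param terms_per_module annotation terms per module.
#' @param coverage fraction of the module's genes each term annotates
#'   (in (0, 1]).
#' @param leak fraction of non-core genes each term additionally annotates
#'   as noise (in [0, 1)).
#' @param seed integer seed.
#' @return list with `table` (an `fmm_annotation_table`), `ontology` (an
#'   `fmm_ontology`), and `term_modules` (named character vector
#'   term -> module id; mid-level and root terms are absent from it).
#' @export
module_annotations <- function(modules, terms_per_module = 5L,
                               coverage = 0.2, leak = 0.005, seed = 1L) {
  if (!(coverage > 0 && coverage <= 1)) stop("`coverage` must be in (0, 1]")
  if (!(leak >= 0 && leak < 1)) stop("`leak` must be in [0, 1)")
  mods <- unique(modules)
  genes <- names(modules)
  root <- "TOY:0000000"
  mid <- stats::setNames(sprintf("TOY:%07d", seq_along(mods)), mods)
  term_ids <- character(); term_parent <- character(); term_mod <- character()
  for (m in mods) {
    for (t in seq_len(terms_per_module)) {
      id <- sprintf("TOY:%07d", 1000L + (match(m, mods) - 1L) *
                      terms_per_module + t)
      term_ids <- c(term_ids, id)
      term_parent <- c(term_parent, mid[[m]])
      term_mod <- c(term_mod, m)
    }
  }
  all_terms <- c(root, unname(mid), term_ids)
  parents <- c(list(character()), rep(list(root), length(mid)),
               as.list(term_parent))
  names(parents) <- all_terms
  ont <- ontology(all_terms, parents,
                  stats::setNames(rep("biological_process",
                                      length(all_terms)), all_terms))
  local_seed(seed, {
    term <- character(); gene <- character()
    pool <- lapply(stats::setNames(mods, mods),
                   function(m) sample(genes[modules == m]))
    for (idx in seq_along(term_ids)) {
      m <- term_mod[idx]
      inside <- genes[modules == m]
      n_in <- max(1L, round(coverage * length(inside)))
      # deal from the module pool without replacement; refill when empty so
      # overlap appears only once coverage * terms_per_module exceeds 1
      if (length(pool[[m]]) < n_in) {
        pool[[m]] <- c(pool[[m]], sample(setdiff(inside, pool[[m]])))
      }
      take <- pool[[m]][seq_len(n_in)]
      pool[[m]] <- pool[[m]][-seq_len(n_in)]
      noise_pool <- setdiff(genes, take)
      n_out <- round(leak * length(noise_pool))
      picked <- c(take, if (n_out > 0L) sample(noise_pool, n_out))
      term <- c(term, rep(term_ids[idx], length(picked)))
      gene <- c(gene, picked)
    }
    list(table = annotation_table(term, gene), ontology = ont,
         term_modules = stats::setNames(term_mod, term_ids))
  })
}

#' Degree-preserving network randomization
#'
#' Applies double-edge swaps that keep every gene's degree exactly while
#' destroying all higher-order structure (modules, clustering). The standard
#' rewired null model for "is this structure more than degrees?" questions.
#'
#' @param network an `fmm_network`.
#' @param n_swaps number of attempted swaps (default 10 x number of edges).
#' @param seed integer seed.
#' @return a rewired `fmm_network` with the same degree sequence.
#' @export
rewire_network <- function(network, n_swaps = NULL, seed = 1L) {
  if (is.null(n_swaps)) n_swaps <- 10L * nrow(network$edges)
  g <- as_igraph(network)
  g2 <- local_seed(seed,
    igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                             niter = n_swaps)))
  out <- from_igraph(g2)
  # double swaps preserve every degree, so the node set cannot change
  stopifnot(identical(sort(out$nodes), sort(network$nodes)))
  out
}

#' Perturb selected modules of a network
#'
#' Builds the "case" twin of a control network by dismantling the target
#' modules' internal cohesion while preserving every gene's degree. A
#' fraction `intensity` of the edges internal to the target modules is
#' rewired by double-edge swaps against inter-module (cross) edges: each
#' swap turns one target-internal edge and one cross edge into two cross
#' edges, scattering the target genes' connectivity over the whole network.
#' Because swap partners are never internal to an untouched module, the
#' internal edge set of every untouched module is exactly that of the
#' control; swaps that cannot be placed without creating self-loops or
#' duplicate edges are skipped (with a warning when more than half fail).
#'
#' @param network an `fmm_network`.
#' @param modules named character vector gene -> module id.
#' @param target_modules module ids to perturb.
#' @param intensity fraction of target-internal edges to rewire
#'   (in (0, 1]).
#' @param seed integer seed.
#' @return perturbed `fmm_network`.
#' @export
perturb_case <- function(network, modules, target_modules, intensity = 0.8,
                         seed = 1L) {
  if (length(target_modules) == 0L) stop("`target_modules` must be non-empty")
  unknown <- setdiff(target_modules, unique(modules))
  if (length(unknown) > 0L) stop("unknown module(s): ",
                                 paste(unknown, collapse = ", "))
  if (!(intensity > 0 && intensity <= 1)) stop("`intensity` must be in (0, 1]")
  edges <- network$edges
  mod1 <- modules[edges[, 1L]]
  mod2 <- modules[edges[, 2L]]
  internal_target <- which(mod1 == mod2 & mod1 %in% target_modules)
  cross <- which(mod1 != mod2)           # never internal to any module
  n_rewire <- round(intensity * length(internal_target))
  if (n_rewire < 1L || length(cross) == 0L) return(network)
  local_seed(seed, {
    selected <- sample(internal_target, n_rewire)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    present <- new.env(parent = emptyenv())
    for (r in seq_len(nrow(edges))) {
      assign(key(edges[r, 1L], edges[r, 2L]), TRUE, envir = present)
    }
    cross_pool <- cross
    failed <- 0L
    for (e in selected) {
      done <- FALSE
      for (try in seq_len(20L)) {
        p <- sample(cross_pool, 1L)
        u1 <- edges[e, 1L]; v1 <- edges[e, 2L]
        u2 <- edges[p, 1L]; v2 <- edges[p, 2L]
        if (stats::runif(1) < 0.5) { tmp <- u2; u2 <- v2; v2 <- tmp }
        if (u1 == v2 || u2 == v1) next
        k1 <- key(u1, v2); k2 <- key(u2, v1)
        if (exists(k1, envir = present) || exists(k2, envir = present) ||
            k1 == k2) next
        rm(list = c(key(u1, v1), key(u2, v2)), envir = present)
        assign(k1, TRUE, envir = present)
        assign(k2, TRUE, envir = present)
        edges[e, ] <- c(u1, v2)
        edges[p, ] <- c(u2, v1)
        # both rewired edges are now cross edges
        cross_pool <- union(cross_pool, e)
        done <- TRUE
        break
      }
      if (!done) failed <- failed + 1L
    }
    if (failed > n_rewire / 2) {
      warning("could only place ", n_rewire - failed, " of ", n_rewire,
              " rewiring swaps; perturbation is partial")
    }
    out <- fmm_network(edges)
    stopifnot(identical(sort(out$nodes), sort(network$nodes)))
    out
  })
}

#' Full synthetic case/control scenario with planted ground truth
#'
#' Builds a modular control network with module-aligned annotations and a
#' toy ontology, then a perturbed case twin in which the target modules'
#' connectivity is scrambled. The ground truth determines which annotations
#' should be detected as shifted (those of the perturbed modules) and which
#' genes should receive the highest movement scores (members of the
#' perturbed modules). The perturbed modules' annotations are kept a small
#' minority of all terms (the defaults give 10%) because the two-standard-
#' deviation shifted rule is an outlier detector: a subpopulation of
#' fraction q can only exceed mean + 2 sd of the mixture when
#' q + 2*sqrt(q(1-q)) < 1, i.e. q < 0.2. A single scenario seed fans out to
#' per-stage seeds
#' as `seed + stage index` (network +1, annotations +2, perturbation +3,
#' randomization +4).
#'
#' @param n_modules,module_size,p_in,p_out see
#'   [planted_partition_network()].
#' @param terms_per_module,coverage,leak see [module_annotations()].
#' @param n_target_modules number of modules to perturb (the first ones).
#' @param intensity see [perturb_case()].
#' @param seed scenario seed.
#' @return an `fmm_scenario` list: `control`, `case`, `table`, `ontology`,
#'   `truth` (modules, term_modules, target_modules, case_annotations,
#'   case_genes), `params`, `seed`.
#' @export
synthetic_scenario <- function(n_modules = 12L, module_size = 20L,
                               p_in = 0.4, p_out = 0.015,
                               terms_per_module = 5L, coverage = 0.2,
                               leak = 0.005, n_target_modules = 1L,
                               intensity = 1.0, seed = 1L) {
  pp <- planted_partition_network(n_modules, module_size, p_in, p_out,
                                  seed = seed + 1L)
  ann <- module_annotations(pp$modules, terms_per_module, coverage, leak,
                            seed = seed + 2L)
  target_modules <- sprintf("M%d", seq_len(n_target_modules))
  case <- perturb_case(pp$network, pp$modules, target_modules, intensity,
                       seed = seed + 3L)
  truth <- list(
    modules = pp$modules,
    term_modules = ann$term_modules,
    target_modules = target_modules,
    case_annotations = names(ann$term_modules)[
      ann$term_modules %in% target_modules],
    case_genes = names(pp$modules)[pp$modules %in% target_modules])
  structure(list(control = pp$network, case = case, table = ann$table,
                 ontology = ann$ontology, truth = truth,
                 params = list(n_modules = n_modules,
                               module_size = module_size, p_in = p_in,
                               p_out = p_out,
                               terms_per_module = terms_per_module,
                               coverage = coverage, leak = leak,
                               n_target_modules = n_target_modules,
                               intensity = intensity),
                 seed = as.integer(seed)),
            class = "fmm_scenario")
}

#' @export
print.fmm_scenario <- function(x, ...) {
  cat(sprintf(paste0(
    "fmm_scenario (seed %d): %d modules x %d genes\n",
    "  control: %d edges, case: %d edges, %d annotation terms\n",
    "  perturbed modules: %s\n"),
    x$seed, x$params$n_modules, x$params$module_size,
    nrow(x$control$edges), nrow(x$case$edges),
    length(x$truth$term_modules),
    paste(x$truth$target_modules, collapse = ", ")))
  invisible(x)
}

#' Write a scenario to disk in the standard exchange formats
#'
#' Edge lists as TSV, annotations as two-column TSV, the toy ontology as
#' OBO, and the ground truth and parameters as JSON, so that fixtures
#' exercise the package's real readers.
#'
#' @param scenario an `fmm_scenario`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(scenario$control, file.path(dir, "control.edgelist.tsv"))
  write_edge_list(scenario$case, file.path(dir, "case.edgelist.tsv"))
  write_annotations(scenario$table, file.path(dir, "annotations.tsv"))
  write_obo(scenario$ontology, file.path(dir, "ontology.obo"))
  write_json_manifest(c(scenario$truth,
                        list(params = scenario$params,
                             seed = scenario$seed)),
                      file.path(dir, "truth.json"))
  invisible(dir)
}
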