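# Small graphs and tables built in code, shared across test files.

# path A-B-C
path3_network <- function() fmm_network(rbind(c("A", "B"), c("B", "C")))

# complete graph on the given node names
complete_network <- function(nodes) {
  pr <- t(utils::combn(nodes, 2))
  fmm_network(pr)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# toy ontology: root -> {a, b}; three genes, g1,g2 -> a, g3 -> b
toy_dag <- function() {
  ont <- ontology(c("root", "a", "b"),
                  list(root = character(), a = "root", b = "root"),
                  c(root = "bp", a = "bp", b = "bp"))
  table <- annotation_table(c("a", "a", "b"), c("g1", "g2", "g3"))
  list(ont = ont, table = table)
}

# non-negative matrix with exactly orthonormal columns: disjoint supports
nonneg_orthonormal <- function(n, k, seed = 1) {
  stopifnot(n >= k)
  local_seed_test(seed, {
    block <- sort(rep_len(seq_len(k), n))
    Q <- matrix(0, n, k)
    for (j in seq_len(k)) {
      rows <- which(block == j)
      v <- stats::runif(length(rows), 0.5, 1.5)
      Q[rows, j] <- v / sqrt(sum(v^2))
    }
    Q
  })
}

local_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# symmetric PSD test matrix from planted non-negative orthonormal factors
planted_ppmi_like <- function(n = 30, k = 5, seed = 1) {
  Q <- nonneg_orthonormal(n, k, seed)
  s <- seq(k, 1)
  X <- Q %*% diag(s) %*% t(Q)
  dimnames(X) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  X
}

# a tiny scenario used where full defaults would be slow
small_scenario <- function(seed = 1) {
  synthetic_scenario(n_modules = 4L, module_size = 10L, p_in = 0.5,
                     p_out = 0.05, terms_per_module = 3L, coverage = 0.3,
                     leak = 0.01, n_target_modules = 1L, intensity = 1.0,
                     seed = seed)
}

# mid-size scenario with enough annotation terms for stable rank statistics
mid_scenario <- function(seed = 1) {
  synthetic_scenario(n_modules = 6L, module_size = 12L, p_in = 0.5,
                     p_out = 0.03, terms_per_module = 4L, coverage = 0.25,
                     leak = 0.01, n_target_modules = 1L, intensity = 1.0,
                     seed = seed)
}
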