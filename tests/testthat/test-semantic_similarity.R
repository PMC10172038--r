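test_that("information content follows hand propagation on the toy DAG", {
  toy <- toy_dag()
  ic <- information_content(toy$ont, toy$table)
  # all 3 genes reach the root; a covers g1,g2 -> p = 2/3
  expect_equal(ic$ic[["root"]], 0)
  expect_equal(ic$ic[["a"]], -log(2 / 3))
  expect_equal(ic$ic[["b"]], -log(1 / 3))
})

test_that("terms annotating every gene are uninformative", {
  ont <- ontology(c("r", "x"), list(r = character(), x = "r"),
                  c(r = "bp", x = "bp"))
  tab <- annotation_table(rep("x", 4), sprintf("g%d", 1:4))
  ic <- information_content(ont, tab)
  expect_equal(ic$ic[["x"]], 0)
})

test_that("unknown annotation terms are dropped with a warning", {
  toy <- toy_dag()
  tab <- annotation_table(c("a", "b", "nope"), c("g1", "g3", "g9"))
  expect_warning(ic <- information_content(toy$ont, tab), "dropped")
  expect_false("nope" %in% names(ic$ic))
  only_bad <- annotation_table("nope", "g1")
  expect_error(information_content(toy$ont, only_bad), "no annotation term")
})

test_that("Lin similarity matches hand computations on the toy DAG", {
  toy <- toy_dag()
  ic <- information_content(toy$ont, toy$table)
  expect_equal(lin_similarity("a", "a", ic, toy$ont), 1)
  # MICA of a and b is the root with ic 0
  expect_equal(lin_similarity("a", "b", ic, toy$ont), 0)
  expect_equal(lin_similarity("root", "root", ic, toy$ont), 0)
  expect_error(lin_similarity("a", "ghost", ic, toy$ont), "ghost")
})

test_that("terms in different namespaces have zero similarity", {
  ont <- ontology(c("r1", "r2", "x", "y"),
                  list(r1 = character(), r2 = character(), x = "r1",
                       y = "r2"),
                  c(r1 = "bp", r2 = "mf", x = "bp", y = "mf"))
  tab <- annotation_table(c("x", "y", "x"), c("g1", "g2", "g3"))
  ic <- information_content(ont, tab)
  expect_equal(lin_similarity("x", "y", ic, ont), 0)
})

test_that("deeper shared ancestors give larger similarity (chain property)", {
  # root -> mid -> {x, y}; extra sibling branch keeps mid informative
  ont <- ontology(c("root", "mid", "other", "x", "y"),
                  list(root = character(), mid = "root", other = "root",
                       x = "mid", y = "mid"),
                  stats::setNames(rep("bp", 5), c("root", "mid", "other",
                                                  "x", "y")))
  tab <- annotation_table(c("x", "y", "other", "other"),
                          c("g1", "g2", "g3", "g4"))
  ic <- information_content(ont, tab)
  sib <- lin_similarity("x", "y", ic, ont)       # MICA = mid
  cross <- lin_similarity("x", "other", ic, ont) # MICA = root
  expect_gt(sib, cross)
  expect_equal(cross, 0)
  # brute-force MICA oracle: maximize ic over explicitly enumerated
  # common ancestors
  anc_x <- term_ancestors(ont, "x"); anc_y <- term_ancestors(ont, "y")
  mica_ic <- max(ic$ic[intersect(anc_x, anc_y)], na.rm = TRUE)
  expect_equal(sib, 2 * mica_ic / (ic$ic[["x"]] + ic$ic[["y"]]))
})

test_that("mean pairwise Lin averages the cross product correctly", {
  ont <- ontology(c("root", "m1", "m2", "a1", "a2", "b1", "b2"),
                  list(root = character(), m1 = "root", m2 = "root",
                       a1 = "m1", a2 = "m1", b1 = "m2", b2 = "m2"),
                  stats::setNames(rep("bp", 7),
                                  c("root", "m1", "m2", "a1", "a2", "b1",
                                    "b2")))
  tab <- annotation_table(c("a1", "a2", "b1", "b2"),
                          c("g1", "g2", "g3", "g4"))
  ic <- information_content(ont, tab)
  # enumeration oracle over the 2 x 2 cross product
  vals <- c(lin_similarity("a1", "b1", ic, ont),
            lin_similarity("a1", "b2", ic, ont),
            lin_similarity("a2", "b1", ic, ont),
            lin_similarity("a2", "b2", ic, ont))
  expect_equal(mean_pairwise_lin(c("a1", "a2"), c("b1", "b2"), ic, ont),
               mean(vals))
  # identical sets exclude self-pairs
  expect_equal(mean_pairwise_lin(c("a1", "a2"), c("a1", "a2"), ic, ont),
               lin_similarity("a1", "a2", ic, ont))
  expect_error(mean_pairwise_lin("a1", "a1", ic, ont), "no term pairs")
  expect_error(mean_pairwise_lin(character(), "a1", ic, ont), "non-empty")
})

test_that("lin_similarity is symmetric in its arguments", {
  sc <- small_scenario(3)
  ic <- information_content(sc$ontology, sc$table)
  terms <- names(sc$truth$term_modules)
  local_seed_test(12, {
    for (i in 1:10) {
      pick <- sample(terms, 2)
      expect_equal(lin_similarity(pick[1], pick[2], ic, sc$ontology),
                   lin_similarity(pick[2], pick[1], ic, sc$ontology))
    }
  })
})

test_that("OBO round trip preserves structure and drops obsolete terms", {
  sc <- small_scenario(2)
  path <- tempfile(fileext = ".obo")
  write_obo(sc$ontology, path)
  back <- read_obo(path)
  expect_setequal(back$terms, sc$ontology$terms)
  expect_identical(back$parents[sc$ontology$terms],
                   sc$ontology$parents[sc$ontology$terms])

  lines <- c("format-version: 1.2", "",
             "[Term]", "id: T:1", "namespace: bp", "",
             "[Term]", "id: T:2", "namespace: bp", "is_a: T:1 ! parent",
             "", "[Term]", "id: T:3", "namespace: bp", "is_a: T:1",
             "is_obsolete: true",
             "", "[Typedef]", "id: part_of")
  p <- write_lines_tmp(lines, ".obo")
  ont <- read_obo(p)
  expect_setequal(ont$terms, c("T:1", "T:2"))
  expect_equal(ont$parents[["T:2"]], "T:1")
  expect_equal(ont$roots, "T:1")
})

test_that("cyclic is_a graphs are rejected", {
  expect_error(ontology(c("a", "b"), list(a = "b", b = "a"),
                        c(a = "bp", b = "bp")), "cycle")
})
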