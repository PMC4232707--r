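test_that("build_dag derives relations of the toy graph", {
  dag <- toy_dag()
  expect_s3_class(dag, "gene_set_dag")
  expect_equal(dag$m, 6L)
  expect_equal(dag$n_children[["B"]], 3L)
  expect_equal(ancestors(dag, "E"), c("A", "B", "F"))
  expect_equal(offspring(dag, "B"), c("C", "D", "E"))
  expect_equal(dag_parents(dag, "E"), c("B", "F"))
})

test_that("degenerate and invalid DAG inputs are handled", {
  d1 <- build_dag(NULL, list(X = "g1"))
  expect_equal(d1$m, 1L)
  expect_length(ancestors(d1, "X"), 0L)
  expect_length(offspring(d1, "X"), 0L)

  expect_error(
    build_dag(data.frame(parent = c("A", "B"), child = c("B", "A")),
              list(A = "g", B = "g")),
    "cycl")
  expect_error(
    build_dag(data.frame(parent = "A", child = "B"),
              list(A = "g1", B = "g2")),
    "true-path")
  expect_error(
    build_dag(data.frame(parent = "A", child = "B"),
              list(A = "g1", B = character(0))),
    "empty membership")
  expect_error(
    build_dag(data.frame(parent = "A", child = "Z"), list(A = "g1")),
    "endpoint")
})

test_that("annotation propagation repairs subset violations", {
  dag <- build_dag(data.frame(parent = "A", child = "B"),
                   list(A = "g1", B = "g2"), propagate = TRUE)
  expect_setequal(dag$membership$A, c("g1", "g2"))
  expect_equal(dag$membership$B, "g2")
})

test_that("focus level validation enforces FL1 and FL2 and stratifies", {
  dag <- toy_dag()
  fl <- validate_focus_level(dag, c("B", "F"))
  expect_equal(fl$m_F, 2L)
  expect_equal(unname(fl$strata["A"]), "ancestor")
  expect_equal(unname(fl$strata[c("C", "D", "E")]), rep("offspring", 3))

  expect_error(validate_focus_level(dag, c("C", "D", "E", "F")),
               class = "sfl_fl1_error")
  err <- tryCatch(validate_focus_level(dag, c("C", "D", "E", "F")),
                  error = identity)
  expect_true(all(c("F", "E") %in% err$terms))

  expect_error(validate_focus_level(dag, "B"), class = "sfl_fl2_error")
  err2 <- tryCatch(validate_focus_level(dag, "B"), error = identity)
  expect_true("F" %in% err2$terms)

  expect_error(validate_focus_level(dag, "nope"), "unknown")
  expect_error(validate_focus_level(dag, character(0)), "at least one")
})

test_that("strata of a valid focus level partition the term set", {
  set.seed(11)
  for (i in 1:20) {
    dag <- random_generic_dag()
    fl <- validate_focus_level(dag, "root")
    expect_setequal(names(fl$strata), dag$terms)
    expect_false(anyNA(fl$strata))
    # an intermediate antichain focus level: the children of the root
    kids <- dag_children(dag, "root")
    kids <- kids[vapply(kids, function(k)
      !any(kids %in% dag$offspring[[k]]), TRUE)]
    if (length(kids) && setequal(
          unique(c(unlist(dag$ancestors[kids]), unlist(dag$offspring[kids]), kids)),
          dag$terms)) {
      fl2 <- validate_focus_level(dag, kids)
      expect_equal(sort(table(factor(fl2$strata,
        c("ancestor", "focus", "offspring")))[["focus"]]), length(kids))
    }
  }
})

test_that("infer_hasse recovers the covering relation", {
  # chain keeps only covering edges
  dag <- infer_hasse(list(S1 = c("a", "b", "c"), S2 = c("a", "b"), S3 = "a"))
  expect_equal(dag$edges,
               data.frame(parent = c("S1", "S2"), child = c("S2", "S3"),
                          stringsAsFactors = FALSE))
  # disjoint sets give an edgeless graph
  expect_equal(nrow(infer_hasse(list(A = "x", B = "y", C = "z"))$edges), 0L)
  # duplicates are rejected
  expect_error(infer_hasse(list(A = c("x", "y"), B = c("y", "x"))),
               "duplicate")
})

test_that("infer_hasse on the 14-set system matches the printed structure", {
  dag <- sim2_dag()
  expect_equal(dag_children(dag, "GO:01"), c("GO:02", "GO:03", "GO:04"))
  expect_equal(dag_parents(dag, "GO:07"), c("GO:02", "GO:03"))
  expect_equal(dag_parents(dag, "GO:13"), c("GO:10", "GO:11"))
  expect_equal(dag_parents(dag, "GO:14"), c("GO:11", "GO:12"))
})

test_that("transitive closure of the Hasse diagram is the inclusion order", {
  set.seed(21)
  for (i in 1:10) {
    dag <- random_generic_dag()
    mem <- dag$membership
    for (a in dag$terms) for (b in dag$terms) {
      if (a == b) next
      strict_super <- length(mem[[b]]) < length(mem[[a]]) &&
        all(mem[[b]] %in% mem[[a]])
      expect_equal(b %in% dag$offspring[[a]], strict_super,
                   info = paste(a, b))
    }
  }
})

test_that("atoms partition the gene universe by signature", {
  blocks <- atoms(sim2_genesets())
  expect_length(blocks, 11L)
  sizes <- vapply(blocks, function(b) length(b$genes), 1L)
  expect_equal(sum(sizes), 100L)
  # genes 72-79 are exactly one block; genes 71 and 80 share a block
  sig13 <- vapply(blocks, function(b) "g072" %in% b$genes, TRUE)
  expect_setequal(blocks[[which(sig13)]]$genes, sprintf("g%03d", 72:79))
  shared <- vapply(blocks, function(b) "g071" %in% b$genes, TRUE)
  expect_true("g080" %in% blocks[[which(shared)]]$genes)

  expect_length(atoms(list(A = "x", B = "y")), 2L)
  expect_length(atoms(list(A = "x", B = "x")), 1L)
})

test_that("each membership is the union of its atom blocks", {
  set.seed(31)
  for (i in 1:10) {
    mem <- random_generic_dag()$membership
    blocks <- atoms(mem)
    for (t in names(mem)) {
      in_blocks <- unlist(lapply(blocks, function(b)
        if (t %in% b$terms) b$genes else NULL))
      expect_setequal(in_blocks, mem[[t]])
    }
  }
})

test_that("merge_duplicate_sets collapses with a warning", {
  expect_warning(out <- merge_duplicate_sets(
    list(B = c("x", "y"), A = c("y", "x"), C = "z")), "merged")
  expect_named(out, c("A", "C"))
})

test_that("prune_small_sets reroutes edges transitively", {
  dag <- infer_hasse(list(A = paste0("g", 1:10), B = paste0("g", 1:3),
                          C = paste0("g", 1:8), D = paste0("g", 1:6)))
  # chain A > C > D > B; dropping D (min 7) must leave C -> nothing below
  pr <- prune_small_sets(dag, min_size = 7L)
  expect_setequal(pr$terms, c("A", "C"))
  expect_equal(pr$edges, data.frame(parent = "A", child = "C",
                                    stringsAsFactors = FALSE))
  pr2 <- prune_small_sets(dag, min_size = 4L)  # drops only B
  expect_true("D" %in% dag_children(pr2, "C"))
  expect_error(prune_small_sets(dag, min_size = 99L), "no terms")
})
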