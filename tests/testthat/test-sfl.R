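test_that("the SFL graph of the toy DAG carries the prescribed weights", {
  dag <- toy_dag()
  fl <- validate_focus_level(dag, c("B", "F"))
  g <- build_sfl_graph(dag, fl, 0.05)
  expect_setequal(g$hypotheses, c("B", "C", "D", "E", "F"))
  expect_equal(unname(g$alpha0[c("B", "F")]), c(0.025, 0.025))
  expect_equal(unname(g$alpha0[c("C", "D", "E")]), rep(0, 3))
  expect_equal(unname(g$G["B", c("C", "D", "E")]), rep(1 / 3, 3))
  expect_equal(unname(g$G["F", "E"]), 1)
  for (t in c("C", "D", "E"))
    expect_equal(unname(g$G[t, c("B", "F")]), c(0.5, 0.5))
  expect_true(validate_regularity(g)$ok)
})

test_that("degenerate SFL graphs follow the construction rules", {
  d1 <- build_dag(NULL, list(X = "g"))
  f1 <- validate_focus_level(d1, "X")
  g1 <- build_sfl_graph(d1, f1, 0.05)
  expect_equal(unname(g1$alpha0), 0.05)
  expect_equal(sum(g1$G), 0)

  # single focus term at the root: every terminal sends weight 1 back
  dag <- sim2_dag()
  fl <- validate_focus_level(dag, "root")
  g <- build_sfl_graph(dag, fl, 0.05)
  expect_equal(unname(g$alpha0["GO:01"]), 0.05)
  terminals <- g$hypotheses[rowSums(g$G) > 0 &
    vapply(g$hypotheses, function(t)
      length(intersect(dag$children[[t]], g$hypotheses)) == 0L, TRUE)]
  for (t in terminals) expect_equal(unname(g$G[t, "GO:01"]), 1)
})

test_that("top-down cascade on a two-term chain follows the focus gate", {
  dag <- build_dag(data.frame(parent = "root", child = "kid"),
                   list(root = c("g1", "g2"), kid = "g1"))
  fl <- validate_focus_level(dag, "root")
  expect_setequal(run_topdown(dag, fl, c(root = 0.01, kid = 0.04), 0.05),
                  c("root", "kid"))
  expect_length(run_topdown(dag, fl, c(root = 0.2, kid = 0.001), 0.05), 0L)
  expect_error(run_topdown(dag, fl, c(root = 0.01), 0.05), "missing p-values")
})

test_that("shortcut equals the closed-test oracle on generic-position DAGs", {
  set.seed(777)
  for (b in 1:60) {
    dag <- random_generic_dag()
    fl <- validate_focus_level(dag, "root")
    g <- build_sfl_graph(dag, fl, 0.05)
    p <- setNames(runif(dag$m)^2, dag$terms)
    short <- run_topdown(dag, fl, p, 0.05)
    orc <- closed_test_oracle(g, hypothesis_family(dag$membership), p)
    expect_setequal(short, orc$rejected)
  }
})

test_that("shortcut rejections are contained in the closed test's", {
  # on degenerate families (terms exactly unions of others) the shortcut
  # may be conservative but must never reject more than the closed test
  set.seed(888)
  for (b in 1:40) {
    dag <- random_nested_dag()
    fl <- validate_focus_level(dag, "root")
    g <- build_sfl_graph(dag, fl, 0.05)
    p <- setNames(runif(dag$m)^2, dag$terms)
    short <- run_topdown(dag, fl, p, 0.05)
    orc <- closed_test_oracle(g, hypothesis_family(dag$membership), p)
    expect_true(all(short %in% orc$rejected))
  }
})

test_that("bottom-up inheritance declares and adjusts ancestors", {
  dag <- toy_dag()
  fl <- validate_focus_level(dag, c("B", "F"))
  p <- c(A = 0.5, B = 0.01, C = 0.9, D = 0.9, E = 0.9, F = 0.2)
  td <- run_topdown(dag, fl, p, 0.05)
  expect_true("B" %in% td)
  bu <- run_bottomup(dag, fl, p, 0.05, td)
  expect_equal(bu$term, "A")
  expect_true(bu$rejected)
  # Holm on (0.01, 0.2) -> (0.02, 0.2); A inherits the minimum
  expect_equal(bu$adjusted_p, 0.02)

  bu0 <- run_bottomup(dag, fl, p, 0.05, character(0))
  expect_false(bu0$rejected)
})

test_that("sfl on an offspring-free focus level is exactly Holm", {
  set.seed(99)
  for (i in 1:20) {
    m <- sample(3:7, 1)
    terms <- paste0("t", seq_len(m))
    mem <- setNames(lapply(seq_len(m), function(i) paste0("g", i)), terms)
    dag <- build_dag(NULL, mem)
    p <- setNames(runif(m)^2, terms)
    res <- sfl(dag, p, focus = terms, alpha = 0.05, min_set_size = 1L)
    holm <- p.adjust(p, "holm")
    expect_setequal(res$term[res$rejected], terms[holm <= 0.05])
    # bisection resolves adjusted p to ~1e-6 absolute
    expect_true(all(abs(res$adjusted_p[match(terms, res$term)] - holm) < 2e-6))
  }
})

test_that("sfl results are coherent and consistent with their own flags", {
  dag <- toy_dag()
  p <- c(A = 0.001, B = 0.004, C = 0.02, D = 0.9, E = 0.6, F = 0.9)
  res <- sfl(dag, p, focus = "root", alpha = 0.05, min_set_size = 1L)
  expect_s3_class(res, "sfl_result")
  rej <- res$term[res$rejected]
  for (t in rej) expect_true(all(ancestors(dag, t) %in% rej))
  # rejected iff adjusted p below alpha (bisection tolerance)
  expect_equal(res$rejected, res$adjusted_p <= 0.05 + 1e-5)
  # adjusted p nondecreasing from parent to child below the focus
  for (i in seq_len(nrow(dag$edges))) {
    pa <- dag$edges$parent[i]; ch <- dag$edges$child[i]
    expect_gte(res$adjusted_p[res$term == ch] + 1e-6,
               res$adjusted_p[res$term == pa])
  }
})

test_that("all-ones p-values reject nothing and adjust to one", {
  dag <- toy_dag()
  p <- setNames(rep(1, 6), dag$terms)
  res <- sfl(dag, p, focus = "root", alpha = 0.05, min_set_size = 1L)
  expect_false(any(res$rejected))
  expect_equal(res$adjusted_p, rep(1, 6))
})

test_that("rejection sets are nested in the level alpha", {
  set.seed(66)
  dag <- sim2_dag()
  fl <- validate_focus_level(dag, "root")
  for (i in 1:5) {
    p <- setNames(runif(14)^3, dag$terms)
    prev <- character(0)
    for (a in c(0.01, 0.05, 0.2)) {
      cur <- run_topdown(dag, fl, p, a)
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("min-set-size pruning is applied before focus validation", {
  mem <- list(A = paste0("g", 1:10), B = paste0("g", 1:6), C = paste0("g", 1:2))
  dag <- infer_hasse(mem)
  p <- c(A = 0.001, B = 0.002, C = 0.003)
  res <- sfl(dag, p, focus = "root", alpha = 0.05, min_set_size = 5L)
  expect_setequal(res$term, c("A", "B"))
  expect_true(all(res$rejected))
})

test_that("automatic focus selection is an explicit unimplemented stub", {
  expect_error(select_focus_level(toy_dag()), "not implemented")
})
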