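test_that("regularity validation catches each condition", {
  h <- c("H1", "H2", "H3", "H4")
  a <- 0.05
  # the partially nested example graph passes
  expect_true(validate_regularity(nested4_graph(a))$ok)

  G <- matrix(0, 4, 4, dimnames = list(h, h))
  G[1, 2:4] <- 0.4  # row sum 1.2
  bad <- weighted_test_graph(setNames(rep(a / 4, 4), h), G, a, validate = FALSE)
  v <- validate_regularity(bad)
  expect_false(v$ok)
  expect_match(paste(v$violations, collapse = " "), "row sum")

  G2 <- matrix(0, 4, 4, dimnames = list(h, h))
  G2[2, 2] <- 0.1
  v2 <- validate_regularity(
    weighted_test_graph(setNames(rep(a / 4, 4), h), G2, a, validate = FALSE))
  expect_match(paste(v2$violations, collapse = " "), "diagonal")

  v3 <- validate_regularity(
    weighted_test_graph(setNames(rep(a, 4), h),
                        matrix(0, 4, 4, dimnames = list(h, h)), a,
                        validate = FALSE))
  expect_match(paste(v3$violations, collapse = " "), "condition 1")
})

test_that("reject_update transfers threshold mass along edges", {
  a <- 0.05
  # full transfer along a single edge
  g <- weighted_test_graph(c(x = a, y = 0),
                           matrix(c(0, 0, 1, 0), 2, 2,
                                  dimnames = list(c("x", "y"), c("x", "y"))), a)
  st <- reject_update(new_sequential_state(g), "x")
  expect_equal(unname(st$alpha["y"]), a)
  expect_equal(sum(st$G), 0)

  # the Holm step: symmetric 3-node graph, reject one node
  g3 <- holm_graph(c("a", "b", "c"), a)
  st3 <- reject_update(new_sequential_state(g3), "a")
  expect_equal(unname(st3$alpha[c("b", "c")]), rep(a / 2, 2))
  expect_equal(unname(st3$G["b", "c"]), 1)
  expect_equal(unname(st3$G["c", "b"]), 1)

  # a node with no outgoing edges loses its mass
  g0 <- weighted_test_graph(c(x = a / 2, y = a / 2),
                            matrix(0, 2, 2, dimnames = list(c("x", "y"),
                                                            c("x", "y"))), a)
  st0 <- reject_update(new_sequential_state(g0), "x")
  expect_equal(unname(st0$alpha["y"]), a / 2)

  expect_error(reject_update(st0, "x"), "already rejected")
})

test_that("sequential_reject reproduces Holm's procedure", {
  g <- holm_graph(c("h1", "h2", "h3"), 0.05)
  st <- sequential_reject(g, c(h1 = 0.001, h2 = 0.02, h3 = 0.9))
  expect_setequal(st$rejected, c("h1", "h2"))
  expect_equal(sequential_reject(g, c(h1 = 1, h2 = 1, h3 = 1))$rejected,
               character(0))
})

test_that("Holm equivalence holds for random p on the complete graph", {
  set.seed(101)
  for (i in 1:50) {
    m <- sample(2:8, 1)
    h <- paste0("h", seq_len(m))
    p <- setNames(runif(m)^sample(1:3, 1), h)
    st <- sequential_reject(holm_graph(h, 0.05), p)
    holm_rej <- h[p.adjust(p, "holm") <= 0.05]
    expect_setequal(st$rejected, holm_rej)
  }
})

test_that("threshold mass is conserved or lost, never created", {
  set.seed(123)
  for (i in 1:20) {
    m <- sample(3:6, 1)
    h <- paste0("h", seq_len(m))
    a0 <- runif(m); a0 <- 0.05 * a0 / sum(a0)
    G <- matrix(runif(m * m), m, m); diag(G) <- 0
    G <- G / pmax(rowSums(G), 1) * runif(1)
    dimnames(G) <- list(h, h)
    g <- weighted_test_graph(setNames(a0, h), G, 0.05)
    st <- new_sequential_state(g)
    for (j in sample(h, m - 1)) {
      st <- reject_update(st, j)
      expect_lte(sum(st$alpha[st$active]), 0.05 + 1e-12)
      v <- validate_regularity(
        weighted_test_graph(st$alpha[st$active],
                            st$G[st$active, st$active, drop = FALSE],
                            0.05, validate = FALSE))
      expect_true(v$ok)
    }
  }
})

test_that("final rejection set is invariant to rejection order", {
  set.seed(202)
  for (i in 1:20) {
    m <- sample(3:6, 1)
    h <- paste0("h", seq_len(m))
    a0 <- runif(m); a0 <- 0.05 * a0 / sum(a0)
    G <- matrix(runif(m * m), m, m); diag(G) <- 0
    G <- G / pmax(rowSums(G), 1)
    dimnames(G) <- list(h, h)
    g <- weighted_test_graph(setNames(a0, h), G, 0.05)
    p <- setNames(runif(m)^2, h)
    ref <- sort(sequential_reject(g, p)$rejected)
    # randomized greedy: repeatedly reject any qualifying hypothesis
    for (rep in 1:3) {
      st <- new_sequential_state(g)
      repeat {
        ok <- st$active & st$alpha > 0 & p <= st$alpha + 1e-12
        if (!any(ok)) break
        st <- reject_update(st, sample(names(ok)[ok], 1))
      }
      expect_equal(sort(st$rejected), ref)
    }
  }
})

test_that("unrestricted sequential procedure equals the closed test", {
  set.seed(303)
  for (i in 1:60) {
    m <- sample(3:5, 1)
    h <- paste0("h", seq_len(m))
    a0 <- runif(m); a0 <- 0.05 * a0 / sum(a0)
    G <- matrix(runif(m * m), m, m); diag(G) <- 0
    G <- G / pmax(rowSums(G), 1)
    dimnames(G) <- list(h, h)
    g <- weighted_test_graph(setNames(a0, h), G, 0.05)
    fam <- hypothesis_family(setNames(as.list(paste0("e", seq_len(m))), h))
    p <- setNames(runif(m)^2, h)
    st <- sequential_reject(g, p)
    orc <- closed_test_oracle(g, fam, p)
    expect_setequal(st$rejected, orc$rejected)
  }
})

test_that("scaling thresholds down yields nested rejection sets", {
  set.seed(404)
  for (i in 1:20) {
    m <- 5
    h <- paste0("h", seq_len(m))
    a0 <- runif(m); a0 <- 0.05 * a0 / sum(a0)
    G <- matrix(runif(m * m), m, m); diag(G) <- 0
    G <- G / pmax(rowSums(G), 1)
    dimnames(G) <- list(h, h)
    p <- setNames(runif(m)^2, h)
    g1 <- weighted_test_graph(setNames(a0, h), G, 0.05)
    big <- sequential_reject(g1, p)$rejected
    for (c in c(0.5, 0.1)) {
      gc <- weighted_test_graph(setNames(a0 * c, h), G, 0.05 * c)
      small <- sequential_reject(gc, p)$rejected
      expect_true(all(small %in% big))
    }
  }
})
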