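#' A family of elementary hypotheses with evidence-set encoding
#'
#' Each elementary hypothesis is represented by an *evidence set*: for a
#' gene-set null ("no gene in the set is differentially expressed") the
#' evidence set is the term's gene membership, and implication corresponds
#' to evidence-set superset: `H_i` implies `H_j` iff
#' `evidence(i) >= evidence(j)`.  An intersection hypothesis `H_I` is
#' represented by the union of the evidence sets over `I`, and two index
#' sets describe the same hypothesis exactly when those unions coincide.
#' Abstract nested families (one-sided parameter hypotheses and the like)
#' are encoded by hand-assigned tokens with the same convention.
#'
#' @param evidence named list of nonempty evidence sets (atomic vectors).
#' @return object of class `hypothesis_family`.
#' @examples
#' # two one-sided nulls per parameter, the stricter one implying the weaker
#' fam <- hypothesis_family(list(H1 = c("a1", "a2"), H2 = "a1",
#'                               H3 = c("b1", "b2"), H4 = "b1"))
#' close_family(fam)$n_nodes  # 8, not 2^4 - 1
#' @export
hypothesis_family <- function(evidence) {
  if (is.null(names(evidence)) || anyDuplicated(names(evidence)))
    stop("'evidence' must be a uniquely named list")
  if (any(!vapply(evidence, length, 1L)))
    stop("evidence sets must be nonempty")
  evidence <- lapply(evidence, function(e) sort(unique(as.character(e))))
  structure(list(hypotheses = names(evidence), m = length(evidence),
                 evidence = evidence),
            class = "hypothesis_family")
}

#' @export
print.hypothesis_family <- function(x, ...) {
  cat("hypothesis_family:", x$m, "elementary hypotheses\n")
  invisible(x)
}

# Canonical minimal generating index set of an intersection hypothesis:
# the minimum-cardinality subcollection of `candidates` whose evidence
# union equals `target`, searched among the maximal candidates only
# (dropping any candidate whose evidence lies inside another's never
# increases a cover) with lexicographic tie-break, so the choice is
# deterministic and shared by the shortcut and the oracle.
min_cover_index <- function(evidence, target) {
  nm <- sort(names(evidence))
  ev <- evidence[nm]
  k <- length(nm)
  if (k == 1L) return(nm)
  is_max <- rep(TRUE, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    if (i != j && is_max[i] && length(ev[[i]]) < length(ev[[j]]) &&
        all(ev[[i]] %in% ev[[j]])) { is_max[i] <- FALSE; break }
  cand <- nm[is_max]
  ev <- ev[cand]
  # candidates covering a gene nobody else covers are in every cover
  tab <- table(unlist(ev, use.names = FALSE))
  forced <- cand[vapply(cand, function(t) any(tab[ev[[t]]] == 1L), TRUE)]
  covered <- unique(unlist(ev[forced], use.names = FALSE))
  left <- setdiff(target, covered)
  if (!length(left)) return(forced)  # already sorted
  free <- setdiff(cand, forced)
  if (length(free) > 22L)
    stop("minimal-cover search too large (", length(free), " free candidates)")
  for (sz in seq_along(free)) {
    hits <- utils::combn(free, sz, function(sel) {
      all(left %in% unlist(ev[sel], use.names = FALSE))
    })
    if (any(hits)) {
      sel <- utils::combn(free, sz)[, which(hits)[1]]
      return(sort(c(forced, sel)))
    }
  }
  stop("internal error: candidates do not cover the target")
}

enum_guard <- function(m) {
  if (m > 20L)
    stop("closure enumeration is limited to 20 generators (2^m subsets); got ", m)
  if (m < 1L) stop("need at least one set")
}

# Shared subset-enumeration core. Returns deduplicated closure nodes.
# sets: named list of sorted unique character vectors.
closure_enumerate <- function(sets) {
  m <- length(sets)
  enum_guard(m)
  nm <- names(sets)
  genes <- sort(unique(unlist(sets, use.names = FALSE)))
  memb <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  if (length(genes) == 1L) memb <- matrix(memb, nrow = 1L, dimnames = list(NULL, nm))
  # containment between generators, for the structural (antichain) count
  cont <- matrix(FALSE, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) if (i != j)
    cont[i, j] <- all(memb[, j] <= memb[, i])

  unions <- vector("list", 2L^m)        # logical gene vectors, by subset code
  node_of <- new.env(hash = TRUE, parent = emptyenv())
  struct_seen <- new.env(hash = TRUE, parent = emptyenv())
  nodes <- list()
  n_structural <- 0L
  bit <- 2^(seq_len(m) - 1)
  for (s in seq_len(2L^m - 1L)) {
    low <- which(bitwAnd(s, bit) != 0)[1]
    rest <- s - bit[low]
    u <- if (rest == 0) memb[, low] else (unions[[rest]] | memb[, low])
    unions[[s]] <- u
    idx <- which(bitwAnd(s, bit) != 0)
    # structural identity: the maximal generators of the subcollection
    maximal <- idx[vapply(idx, function(j)
      !any(cont[setdiff(idx, j), j]), TRUE)]
    skey <- paste(maximal, collapse = ",")
    if (is.null(struct_seen[[skey]])) {
      struct_seen[[skey]] <- TRUE
      n_structural <- n_structural + 1L
    }
    key <- paste(which(u), collapse = ",")
    if (is.null(node_of[[key]])) {
      nodes[[length(nodes) + 1L]] <- list(union = genes[u])
      node_of[[key]] <- length(nodes)
    }
  }
  # canonical minimal generating index set per distinct node
  nodes <- lapply(nodes, function(nd) {
    gen <- nm[vapply(nm, function(t) all(sets[[t]] %in% nd$union), TRUE)]
    nd$index <- min_cover_index(sets[gen], nd$union)
    nd$n_index <- length(nd$index)
    nd
  })
  list(nodes = nodes, n_structural = n_structural, genes = genes)
}

closure_graph <- function(nodes, n_structural, generators) {
  ord <- order(vapply(nodes, function(n) length(n$union), 1L),
               vapply(nodes, function(n) paste(n$union, collapse = "\r"), ""))
  structure(list(nodes = nodes[ord], n_nodes = length(nodes),
                 n_structural = n_structural, generators = generators),
            class = "closure_graph")
}

#' @export
print.closure_graph <- function(x, ...) {
  cat("closure_graph:", x$n_nodes, "distinct nodes (",
      x$n_structural, "before content deduplication ) from",
      length(x$generators), "generators\n")
  invisible(x)
}

#' Close a collection of gene sets under unions
#'
#' Enumerates the unions of every nonempty subcollection and keeps the
#' distinct ones; each node retains one minimal generating index set.
#' Two node counts are reported: `n_nodes` deduplicates by gene content
#' (distinct intersection *hypotheses*, which is what closed testing
#' needs), while `n_structural` identifies a union with the antichain of
#' its maximal generating sets, i.e. the node count of the closed graph as
#' a term-level structure.  The counts differ whenever a set equals a
#' union of others (for example when children partition their parent
#' exactly); in generic position they coincide.
#'
#' Enumeration is limited to 20 generating sets.
#'
#' @param sets named list of nonempty gene vectors.
#' @return a `closure_graph`: list of `nodes` (each with `union`, a
#'   minimal generating `index` set), `n_nodes`, `n_structural`,
#'   `generators`.
#' @examples
#' close_under_unions(list(A = 1:3, B = 1:2, C = 3))$n_nodes
#' @export
close_under_unions <- function(sets) {
  if (is.null(names(sets))) stop("'sets' must be named")
  if (any(!vapply(sets, length, 1L))) stop("sets must be nonempty")
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  enc <- closure_enumerate(sets)
  closure_graph(enc$nodes, enc$n_structural, names(sets))
}

#' Intersection closure of a hypothesis family
#'
#' Computes the closure under intersection of the elementary hypotheses,
#' deduplicated through the evidence-set encoding (the intersection over
#' an index set is represented by the union of the evidence sets).  For
#' an unrestricted family the closure has `2^m - 1` nodes; nesting among
#' the elementary hypotheses makes it smaller.
#'
#' @param family a [hypothesis_family()].
#' @return a `closure_graph` (see [close_under_unions()]).
#' @export
close_family <- function(family) {
  stopifnot(inherits(family, "hypothesis_family"))
  enc <- closure_enumerate(family$evidence)
  closure_graph(enc$nodes, enc$n_structural, family$hypotheses)
}

#' Focus-level closure of a gene-set DAG
#'
#' Closes the graph under unions from the focus level down: each focus
#' term together with its offspring is closed under all unions as a
#' separate subgraph, the per-term closures are merged with content
#' deduplication, and the strict ancestors of the focus level are
#' attached unchanged above.  With the root as focus this coincides with
#' [close_under_unions()] over all terms.
#'
#' @param dag a `gene_set_dag`.
#' @param focus a `focus_level` from [validate_focus_level()].
#' @return a `closure_graph`; ancestor terms appear as nodes whose
#'   `index` is the term itself, marked in the `stratum` field.
#' @export
focus_closure <- function(dag, focus) {
  stopifnot(inherits(dag, "gene_set_dag"), inherits(focus, "focus_level"))
  all_nodes <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  struct_seen <- new.env(hash = TRUE, parent = emptyenv())
  n_structural <- 0L
  for (f in focus$terms) {
    sub <- c(f, dag$offspring[[f]])
    enc <- closure_enumerate(dag$membership[sub])
    for (nd in enc$nodes) {
      key <- paste(nd$union, collapse = "\r")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        nd$stratum <- "closure"
        all_nodes[[length(all_nodes) + 1L]] <- nd
      }
    }
    # structural nodes are counted per identity of maximal generating terms
    skeys <- vapply(enc$nodes, function(nd) paste(nd$index, collapse = ","), "")
    for (k in skeys) if (is.null(struct_seen[[k]])) {
      struct_seen[[k]] <- TRUE
      n_structural <- n_structural + 1L
    }
  }
  anc <- names(focus$strata)[focus$strata == "ancestor"]
  for (a in anc) {
    key <- paste(dag$membership[[a]], collapse = "\r")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      all_nodes[[length(all_nodes) + 1L]] <- list(
        union = dag$membership[[a]], index = a, n_index = 1L,
        stratum = "ancestor")
      n_structural <- n_structural + 1L
    }
  }
  closure_graph(all_nodes, n_structural, dag$terms)
}

#' Local significance levels of an intersection hypothesis
#'
#' The weighted-Bonferroni levels `alpha_i(I)` that the graphical
#' procedure implicitly assigns to the intersection hypothesis indexed by
#' `I`: obtained by removing every hypothesis outside `I` from the graph
#' through the rejection-update rule.  The result does not depend on the
#' removal order (asserted in the test suite, not assumed here) and the
#' levels always sum to at most the overall level.
#'
#' @param graph a [weighted_test_graph()].
#' @param I character vector of hypothesis names (nonempty subset).
#' @param order optional explicit removal order for the complement of `I`
#'   (used by order-invariance checks).
#' @return named numeric vector of local levels over `I`.
#' @export
bretz_local_levels <- function(graph, I, order = NULL) {
  I <- as.character(I)
  if (!length(I)) stop("'I' must be nonempty")
  if (length(setdiff(I, graph$hypotheses)))
    stop("unknown hypotheses in 'I'")
  drop <- setdiff(graph$hypotheses, I)
  if (!is.null(order)) {
    stopifnot(setequal(order, drop))
    drop <- order
  }
  state <- new_sequential_state(graph)
  for (j in drop) state <- reject_update(state, j)
  state$alpha[I]
}

#' Brute-force restricted closed test (the correctness oracle)
#'
#' Runs the closed testing procedure over the deduplicated intersection
#' closure of `family`, using as local test for each closure node the
#' weighted Bonferroni test with levels `alpha_i(I)` derived from `graph`
#' at the node's minimal generating index set: the node is rejected iff
#' some `j` in that set has a positive local level `alpha_j(I)` with
#' `p_j <= alpha_j(I)`.  An elementary hypothesis is rejected iff every
#' closure node implying it (evidence superset) is rejected, and its
#' adjusted p-value is the largest weighted-Bonferroni p-value
#' `min_j p_j * alpha / alpha_j(I)` over those nodes.
#'
#' This is exponential in the family size and exists to verify the
#' sequential shortcut on small graphs, never to analyse data.
#'
#' @param graph a [weighted_test_graph()] whose hypotheses are the
#'   elementary hypotheses of `family`.
#' @param family a [hypothesis_family()].
#' @param p named p-values for the elementary hypotheses.
#' @param tol boundary slack matching [sequential_reject()].
#' @return list with `rejected` (character), `adjusted_p` (named numeric),
#'   and `nodes` (per-closure-node detail data frame).
#' @export
closed_test_oracle <- function(graph, family, p, tol = 1e-12) {
  stopifnot(inherits(graph, "weighted_test_graph"),
            inherits(family, "hypothesis_family"))
  if (!setequal(graph$hypotheses, family$hypotheses))
    stop("graph and family must index the same hypotheses")
  p <- p[family$hypotheses]
  if (any(is.na(p))) stop("missing p-values")
  cl <- close_family(family)

  node_rej <- logical(cl$n_nodes)
  node_p <- numeric(cl$n_nodes)
  for (k in seq_len(cl$n_nodes)) {
    I <- cl$nodes[[k]]$index
    lev <- bretz_local_levels(graph, I)
    pos <- lev > 0
    node_rej[k] <- any(pos & p[I] <= lev + tol)
    node_p[k] <- if (any(pos)) min(1, min(p[I][pos] * graph$alpha / lev[pos]))
                 else 1
  }
  ev <- family$evidence
  rejected <- character(0)
  adj <- setNames(rep(NA_real_, family$m), family$hypotheses)
  for (h in family$hypotheses) {
    implying <- vapply(cl$nodes, function(nd) all(ev[[h]] %in% nd$union), TRUE)
    rej <- all(node_rej[implying])
    adj[h] <- max(node_p[implying])
    if (rej) rejected <- c(rejected, h)
  }
  list(rejected = rejected, adjusted_p = adj,
       nodes = data.frame(
         union_size = vapply(cl$nodes, function(nd) length(nd$union), 1L),
         index = vapply(cl$nodes, function(nd) paste(nd$index, collapse = ","), ""),
         p_node = node_p, rejected = node_rej, stringsAsFactors = FALSE))
}
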