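#' Build and validate a gene-set DAG
#'
#' Constructs the central data object of the package: a directed acyclic
#' graph of gene-set terms (parents more general, children more specific)
#' with a gene membership attached to every term.  All relation sets
#' (parents, children, ancestors, offspring) are computed once here and
#' cached; the object is treated as immutable by every downstream
#' algorithm.
#'
#' Validity requires (i) acyclicity, (ii) the true-path property: the
#' membership of a child is a subset of the membership of each of its
#' parents (so that a non-differentially-expressed parent set logically
#' implies non-differential expression of its children sets), and (iii)
#' nonempty membership for every term.  With `propagate = TRUE` every gene
#' annotated to a term is first copied to all of the term's ancestors,
#' which enforces (ii) by construction.
#'
#' @param edges a two-column data frame or matrix of `parent`, `child`
#'   term identifiers.  May have zero rows for an edgeless graph.
#' @param membership named list; for each term, a character (or atomic)
#'   vector of gene identifiers.  Every edge endpoint must appear in
#'   `names(membership)`.
#' @param propagate logical; if `TRUE`, annotations are propagated upward
#'   to all ancestors before validation.
#' @return an object of class `gene_set_dag`: a list with elements
#'   `terms` (character, lexicographic order), `m`, `edges` (data frame),
#'   `membership`, `parents`, `children`, `ancestors`, `offspring` (named
#'   lists of character vectors, one per term) and `n_children` (named
#'   integer vector).
#' @examples
#' mem <- list(A = c("g1", "g2"), B = "g1")
#' dag <- build_dag(data.frame(parent = "A", child = "B"), mem)
#' ancestors(dag, "B")
#' @seealso [infer_hasse()] to derive the edge set from memberships,
#'   [validate_focus_level()], [sfl()]
#' @export
build_dag <- function(edges, membership, propagate = FALSE) {
  if (is.null(names(membership)) || anyDuplicated(names(membership)))
    stop("'membership' must be a uniquely named list of gene vectors")
  terms <- sort(names(membership))
  membership <- lapply(membership, function(g) sort(unique(as.character(g))))
  membership <- membership[terms]

  edges <- normalise_edges(edges)
  unknown <- setdiff(unique(c(edges$parent, edges$child)), terms)
  if (length(unknown))
    stop("edge endpoints without membership entry: ",
         paste(unknown, collapse = ", "))
  if (any(edges$parent == edges$child))
    stop("self-loop edge detected: ", edges$parent[edges$parent == edges$child][1])
  if (anyDuplicated(paste(edges$parent, edges$child)))
    edges <- unique(edges)

  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = terms)
  if (!igraph::is_dag(g)) {
    cyc <- find_cycle(g)
    stop("edge relation is cyclic; one cycle: ", paste(cyc, collapse = " -> "))
  }

  parents  <- adjacency_list(edges, terms, from = "child",  to = "parent")
  children <- adjacency_list(edges, terms, from = "parent", to = "child")
  ancestors <- reach_list(g, terms, mode = "in")
  offspring <- reach_list(g, terms, mode = "out")

  if (propagate) {
    membership <- propagate_membership(membership, offspring)
  } else {
    for (i in seq_len(nrow(edges))) {
      p <- edges$parent[i]; ch <- edges$child[i]
      if (!all(membership[[ch]] %in% membership[[p]]))
        stop("true-path violation: membership of child '", ch,
             "' is not a subset of parent '", p, "'")
    }
  }
  empty <- terms[vapply(membership[terms], length, 1L) == 0L]
  if (length(empty))
    stop("terms with empty membership: ", paste(empty, collapse = ", "))

  structure(list(
    terms = terms,
    m = length(terms),
    edges = edges,
    membership = membership[terms],
    parents = parents,
    children = children,
    ancestors = ancestors,
    offspring = offspring,
    n_children = vapply(children, length, 1L)
  ), class = "gene_set_dag")
}

normalise_edges <- function(edges) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0L) ||
      (is.matrix(edges) && nrow(edges) == 0L) || length(edges) == 0L)
    return(data.frame(parent = character(0), child = character(0),
                      stringsAsFactors = FALSE))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("'edges' needs columns parent, child")
  edges <- edges[, 1:2]
  names(edges) <- c("parent", "child")
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  rownames(edges) <- NULL
  edges
}

# one directed cycle in a non-DAG igraph, as a vector of term names
find_cycle <- function(g) {
  comp <- igraph::components(g, mode = "strong")
  big <- which(comp$csize > 1L)[1]
  vs <- names(comp$membership)[comp$membership == big]
  v <- vs[1]
  nb <- names(igraph::neighbors(g, v, mode = "out"))
  w <- intersect(nb, vs)[1]
  back <- igraph::shortest_paths(g, from = w, to = v, mode = "out")$vpath[[1]]
  c(v, names(back))
}

adjacency_list <- function(edges, terms, from, to) {
  out <- split(edges[[to]], factor(edges[[from]], levels = terms))
  lapply(out, function(x) sort(unique(x)))
}

reach_list <- function(g, terms, mode) {
  out <- lapply(terms, function(v)
    sort(setdiff(names(igraph::subcomponent(g, v, mode = mode)), v)))
  names(out) <- terms
  out
}

propagate_membership <- function(membership, offspring) {
  terms <- names(membership)
  out <- lapply(terms, function(t)
    sort(unique(unlist(membership[c(t, offspring[[t]])], use.names = FALSE))))
  names(out) <- terms
  out
}

#' @export
print.gene_set_dag <- function(x, ...) {
  cat("gene_set_dag:", x$m, "terms,", nrow(x$edges), "edges,",
      length(unique(unlist(x$membership, use.names = FALSE))), "genes\n")
  roots <- x$terms[vapply(x$parents, length, 1L) == 0L]
  cat("  roots:", paste(head(roots, 5L), collapse = ", "),
      if (length(roots) > 5L) "..." else "", "\n")
  invisible(x)
}

#' Relation accessors for a gene-set DAG
#'
#' Cached transitive relations of a [build_dag()] object.
#' @param dag a `gene_set_dag`
#' @param term a single term identifier
#' @return character vector of term identifiers
#' @export
ancestors <- function(dag, term) dag$ancestors[[match_term(dag, term)]]

#' @rdname ancestors
#' @export
offspring <- function(dag, term) dag$offspring[[match_term(dag, term)]]

#' @rdname ancestors
#' @export
dag_children <- function(dag, term) dag$children[[match_term(dag, term)]]

#' @rdname ancestors
#' @export
dag_parents <- function(dag, term) dag$parents[[match_term(dag, term)]]

match_term <- function(dag, term) {
  if (!term %in% dag$terms) stop("unknown term: ", term)
  term
}

#' Infer the Hasse diagram of a collection of gene sets
#'
#' Derives the DAG edge set as the covering relation of strict set
#' inclusion: an edge `i -> j` is drawn iff `membership(j)` is a strict
#' subset of `membership(i)` and no third set lies strictly between them.
#' Transitive edges are dropped.  Two terms with identical membership are
#' rejected with an error (they would create indistinguishable
#' hypotheses); use [merge_duplicate_sets()] first if collapsing them is
#' acceptable.
#'
#' @param membership named list of nonempty gene vectors.
#' @return a `gene_set_dag` whose edges form the Hasse diagram.
#' @examples
#' dag <- infer_hasse(list(A = c("g1", "g2", "g3"), B = c("g1", "g2"), C = "g1"))
#' dag$edges  # A -> B -> C, no A -> C shortcut
#' @export
infer_hasse <- function(membership) {
  if (is.null(names(membership))) stop("'membership' must be named")
  terms <- sort(names(membership))
  sets <- lapply(membership[terms], function(g) sort(unique(as.character(g))))
  sig <- vapply(sets, paste, "", collapse = "\r")
  if (anyDuplicated(sig)) {
    dup <- split(terms, sig)
    dup <- dup[vapply(dup, length, 1L) > 1L]
    stop("duplicate gene sets: ",
         paste(vapply(dup, paste, "", collapse = " = "), collapse = "; "))
  }
  m <- length(terms)
  incl <- matrix(FALSE, m, m, dimnames = list(terms, terms))
  for (i in seq_len(m)) for (j in seq_len(m)) if (i != j)
    incl[i, j] <- length(sets[[j]]) < length(sets[[i]]) &&
      all(sets[[j]] %in% sets[[i]])
  cover <- incl
  # i covers j unless some k lies strictly between (i > k > j)
  for (k in seq_len(m)) cover[incl[, k], incl[k, ]] <- FALSE
  idx <- which(cover, arr.ind = TRUE)
  edges <- data.frame(parent = terms[idx[, 1]], child = terms[idx[, 2]],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$parent, edges$child), , drop = FALSE]
  rownames(edges) <- NULL
  build_dag(edges, sets)
}

#' Merge terms with identical gene membership
#'
#' Collapses groups of duplicate sets to a single term whose identifier is
#' the lexicographically smallest of the group, with a warning naming the
#' merged terms.  Intended as a pre-processing aid before [infer_hasse()].
#'
#' @param membership named list of gene vectors.
#' @return named list of gene vectors with duplicates collapsed.
#' @export
merge_duplicate_sets <- function(membership) {
  terms <- sort(names(membership))
  sets <- lapply(membership[terms], function(g) sort(unique(as.character(g))))
  sig <- vapply(sets, paste, "", collapse = "\r")
  groups <- split(terms, sig)
  dup <- groups[vapply(groups, length, 1L) > 1L]
  if (length(dup))
    warning("merged duplicate gene sets: ",
            paste(vapply(dup, paste, "", collapse = " = "), collapse = "; "))
  keep <- vapply(groups, `[`, "", 1L)
  out <- sets[keep]
  names(out) <- keep
  out[sort(names(out))]
}

#' Partition the gene universe into atoms
#'
#' Atoms are the blocks of the partition of all annotated genes by
#' membership signature: two genes share a block iff they belong to
#' exactly the same terms.  Every term's membership is a disjoint union of
#' blocks, and every union of terms is a union of blocks, which is why the
#' atoms form a basis of the union-closure of the graph.
#'
#' @param membership named list of nonempty gene vectors.
#' @return a list of blocks, each a list with elements `genes` (character)
#'   and `terms` (the signature: the terms containing those genes).
#'   Blocks are ordered by their smallest gene identifier.
#' @export
atoms <- function(membership) {
  if (!length(membership) || any(!vapply(membership, length, 1L)))
    stop("'membership' must be a list of nonempty sets")
  terms <- sort(names(membership))
  genes <- sort(unique(unlist(membership, use.names = FALSE)))
  inset <- vapply(terms, function(t) genes %in% membership[[t]],
                  logical(length(genes)))
  if (length(genes) == 1L) inset <- matrix(inset, nrow = 1L)
  sig <- apply(inset, 1L, function(r) paste(terms[r], collapse = "\r"))
  blocks <- split(genes, sig)
  blocks <- lapply(blocks, function(g) {
    list(genes = g, terms = strsplit(sig[match(g[1], genes)], "\r")[[1]])
  })
  ord <- order(vapply(blocks, function(b) b$genes[1], ""))
  unname(blocks[ord])
}

#' Drop gene sets below a minimum size
#'
#' Removes every term annotated with fewer than `min_size` genes and
#' reconnects the surviving terms by the covering relation of the original
#' reachability order, so ancestor/offspring relations among kept terms
#' are preserved.  An empty result is an error.
#'
#' @param dag a `gene_set_dag`
#' @param min_size minimum number of genes a term must carry (default 5,
#'   the conventional floor for gene-set testing).
#' @return a `gene_set_dag` on the surviving terms.
#' @export
prune_small_sets <- function(dag, min_size = 5L) {
  keep <- dag$terms[vapply(dag$membership, length, 1L) >= min_size]
  if (!length(keep)) stop("no terms with at least ", min_size, " genes")
  if (length(keep) == dag$m) return(dag)
  m <- length(keep)
  reach <- matrix(FALSE, m, m, dimnames = list(keep, keep))
  for (t in keep) reach[t, intersect(dag$offspring[[t]], keep)] <- TRUE
  cover <- reach
  for (k in keep) cover[reach[, k], reach[k, ]] <- FALSE
  idx <- which(cover, arr.ind = TRUE)
  edges <- data.frame(parent = keep[idx[, 1]], child = keep[idx[, 2]],
                      stringsAsFactors = FALSE)
  build_dag(edges, dag$membership[keep])
}
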