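#' Construct the Short Focus Level test graph
#'
#' Builds the `(alpha, G)` graph of the Short Focus Level procedure over
#' the focus-and-below terms of a gene-set DAG:
#' \itemize{
#'   \item each of the `m_F` focus terms holds local threshold
#'     `alpha / m_F`; every below-focus term starts at 0;
#'   \item every parent-to-child edge of the below-focus subgraph carries
#'     weight `1 / m_i`, where `m_i` is the parent's child count within
#'     that subgraph;
#'   \item every *terminal* term (no children within the subgraph) is
#'     joined back to all focus terms with weight `1 / m_F` -- the
#'     recycling edges -- except that a terminal which is itself a focus
#'     term connects to the other focus terms with weight `1 / (m_F - 1)`
#'     (and keeps its mass if it is the only focus term).
#' }
#' The resulting graph satisfies the regularity conditions by
#' construction (every non-isolated row of weights sums to 1).
#'
#' @param dag a `gene_set_dag`.
#' @param focus a `focus_level` from [validate_focus_level()].
#' @param alpha overall FWER level.
#' @return a [weighted_test_graph()] over the focus-and-below terms.
#' @export
build_sfl_graph <- function(dag, focus, alpha = 0.05) {
  stopifnot(inherits(dag, "gene_set_dag"), inherits(focus, "focus_level"))
  F <- focus$terms
  sub <- sort(unique(c(F, unlist(dag$offspring[F], use.names = FALSE))))
  m_F <- length(F)

  children_sub <- lapply(sub, function(t) intersect(dag$children[[t]], sub))
  names(children_sub) <- sub
  n_child <- vapply(children_sub, length, 1L)
  terminals <- sub[n_child == 0L]

  a0 <- setNames(rep(0, length(sub)), sub)
  a0[F] <- alpha / m_F
  G <- matrix(0, length(sub), length(sub), dimnames = list(sub, sub))
  for (t in sub[n_child > 0L]) G[t, children_sub[[t]]] <- 1 / n_child[t]
  for (t in terminals) {
    if (t %in% F) {
      others <- setdiff(F, t)
      if (length(others)) G[t, others] <- 1 / (m_F - 1)
      # single terminal focus term: no recycling edges, mass retained
    } else {
      G[t, F] <- 1 / m_F
    }
  }
  weighted_test_graph(a0, G, alpha = alpha)
}

#' Top-down pass of the Short Focus Level procedure
#'
#' Runs the restricted sequentially rejective shortcut
#' ([restricted_sequential()]) on the graph of [build_sfl_graph()], with
#' the focus-and-below gene memberships as the evidence sets encoding the
#' logical restrictions.  At every stage the procedure tests the
#' intersection of all not-yet-rejected hypotheses through its canonical
#' minimal representation, so a term is never tested before all of its
#' parents within the focus-and-below subgraph are rejected, and the
#' rejections coincide with the brute-force restricted closed test.
#'
#' @inheritParams build_sfl_graph
#' @param p named p-values covering all focus-and-below terms.
#' @param detail return the full [restricted_sequential()] audit list
#'   instead of the rejection set.
#' @param cache optional environment of memoised level weights (shared
#'   across bisection calls; see [sfl()]).
#' @return character vector of rejected terms, sorted (or the audit list
#'   when `detail = TRUE`).
#' @export
run_topdown <- function(dag, focus, p, alpha = 0.05, detail = FALSE,
                        cache = NULL) {
  graph <- build_sfl_graph(dag, focus, alpha)
  missing <- setdiff(graph$hypotheses, names(p))
  if (length(missing))
    stop("missing p-values for focus-and-below term(s): ",
         paste(missing, collapse = ", "))
  fam <- hypothesis_family(dag$membership[graph$hypotheses])
  out <- restricted_sequential(graph, fam, p[graph$hypotheses],
                               alpha = alpha, cache = cache)
  if (detail) out else sort(out$rejected)
}

#' Bottom-up pass: inheritance above the focus level
#'
#' Every strict ancestor of the focus level is declared significant as
#' soon as any of its focus-level offspring is rejected, following the
#' logical implication that a parent set containing a differentially
#' expressed child set is itself differentially expressed.  Its adjusted
#' p-value is inherited as the minimum over its focus-level offspring of
#' the supplied per-focus-term adjusted p-values; by default these are
#' the Holm-adjusted focus-level p-values.
#'
#' @inheritParams run_topdown
#' @param topdown_rejections rejected set from [run_topdown()].
#' @param focus_adjusted optional named adjusted p-values for the focus
#'   terms to inherit from; defaults to Holm over the focus-level raw
#'   p-values.
#' @return data frame with one row per ancestor term: `term`,
#'   `adjusted_p`, `rejected`.
#' @export
run_bottomup <- function(dag, focus, p, alpha = 0.05, topdown_rejections,
                         focus_adjusted = NULL) {
  F <- focus$terms
  if (is.null(focus_adjusted))
    focus_adjusted <- setNames(p.adjust(p[F], method = "holm"), F)
  anc <- names(focus$strata)[focus$strata == "ancestor"]
  if (!length(anc))
    return(data.frame(term = character(0), adjusted_p = numeric(0),
                      rejected = logical(0), stringsAsFactors = FALSE))
  out <- lapply(anc, function(a) {
    below <- intersect(dag$offspring[[a]], F)
    data.frame(term = a,
               adjusted_p = min(focus_adjusted[below]),
               rejected = any(below %in% topdown_rejections),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$term), , drop = FALSE]
}

#' The Short Focus Level procedure
#'
#' Full pipeline: validates the focus level, runs the top-down restricted
#' graphical test over the focus-and-below terms, propagates rejections
#' upward by inheritance, and reports per-term adjusted p-values.
#' Adjusted p-values for focus-and-below terms are defined as the
#' smallest overall level at which the term would be rejected, resolved
#' by bisection (the rejection set is nested in the level, so this is
#' well defined); ancestors inherit the minimum adjusted p-value of their
#' focus-level offspring, which keeps the reported values coherent along
#' every root-to-leaf path.
#'
#' @param dag a `gene_set_dag`.
#' @param p named vector of per-term raw p-values.
#' @param focus focus term identifiers or `"root"` (default: all
#'   parentless terms, the full top-down approach), or a ready
#'   `focus_level` object.
#' @param alpha overall FWER level, default 0.05.
#' @param min_set_size terms with fewer genes are pruned (with transitive
#'   edge rerouting) before focus validation; default 5, the filter used
#'   for GO analyses.  Set to 0 or 1 to keep all terms.
#' @param adjusted compute adjusted p-values (bisection, tolerance
#'   `2^-20`); if `FALSE` only rejection flags at `alpha` are returned,
#'   which is considerably faster in simulations.
#' @return object of class `sfl_result`: a data frame with columns
#'   `term`, `stratum`, `raw_p`, `adjusted_p`, `rejected`, plus
#'   attributes `alpha` and `focus`.
#' @examples
#' dag <- infer_hasse(list(A = c("g1", "g2"), B = "g1", C = "g2"))
#' p <- c(A = 0.001, B = 0.004, C = 0.6)
#' sfl(dag, p, alpha = 0.05, min_set_size = 1)
#' @export
sfl <- function(dag, p, focus = "root", alpha = 0.05, min_set_size = 5L,
                adjusted = TRUE) {
  stopifnot(inherits(dag, "gene_set_dag"))
  if (min_set_size > 1L) dag <- prune_small_sets(dag, min_set_size)
  focus <- if (inherits(focus, "focus_level")) focus
           else validate_focus_level(dag, focus)
  F <- focus$terms
  sub <- sort(unique(c(F, unlist(dag$offspring[F], use.names = FALSE))))
  missing <- setdiff(dag$terms, names(p))
  if (length(missing))
    stop("missing p-values for: ", paste(missing, collapse = ", "))
  p <- p[dag$terms]
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")

  cache <- new.env(hash = TRUE, parent = emptyenv())
  rejected_sub <- run_topdown(dag, focus, p, alpha, cache = cache)

  adj_sub <- setNames(rep(NA_real_, length(sub)), sub)
  if (adjusted) {
    memo <- new.env(hash = TRUE, parent = emptyenv())
    rejected_at <- function(a) {
      key <- sprintf("%.17g", a)
      got <- memo[[key]]
      if (is.null(got)) {
        got <- run_topdown(dag, focus, p, a, cache = cache)
        memo[[key]] <- got
      }
      got
    }
    for (t in sub) {
      if (!t %in% rejected_at(1 - 1e-9)) { adj_sub[t] <- 1; next }
      lo <- 0; hi <- 1
      for (it in 1:20) {
        mid <- (lo + hi) / 2
        if (t %in% rejected_at(mid)) hi <- mid else lo <- mid
      }
      adj_sub[t] <- hi
    }
  }

  bu <- run_bottomup(dag, focus, p, alpha, rejected_sub,
                     focus_adjusted = if (adjusted) adj_sub[F] else NULL)

  res <- data.frame(term = dag$terms,
                    stratum = unname(focus$strata[dag$terms]),
                    raw_p = unname(p),
                    adjusted_p = NA_real_,
                    rejected = FALSE,
                    stringsAsFactors = FALSE)
  rownames(res) <- dag$terms
  res[sub, "adjusted_p"] <- adj_sub[sub]
  res[sub, "rejected"] <- sub %in% rejected_sub
  if (nrow(bu)) {
    res[bu$term, "adjusted_p"] <- if (adjusted) bu$adjusted_p else NA_real_
    res[bu$term, "rejected"] <- bu$rejected
  }
  rownames(res) <- NULL
  structure(res, class = c("sfl_result", "data.frame"),
            alpha = alpha, focus = F)
}

#' @export
print.sfl_result <- function(x, ...) {
  cat("Short Focus Level result: alpha =", attr(x, "alpha"),
      "; focus level:", paste(attr(x, "focus"), collapse = ", "), "\n")
  cat(sum(x$rejected), "of", nrow(x), "terms rejected\n")
  NextMethod()
}
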