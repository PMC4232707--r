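#' Weighted test graph for graphical Bonferroni testing
#'
#' The pair `(alpha, G)` of a graphical sequentially rejective multiple
#' test: each hypothesis `i` holds a local threshold `alpha_i` (an
#' absolute level, not a fraction of the overall level) and directed edge
#' weights `g_ij` say what share of `alpha_i` flows to hypothesis `j` when
#' `i` is rejected.  Regularity requires `sum(alpha_i) <= alpha`,
#' `0 <= g_ij <= 1`, `g_ii = 0` and row sums of `G` at most 1.
#'
#' @param alpha0 named numeric vector of initial local thresholds.
#' @param G square numeric matrix of edge weights with dimnames matching
#'   `names(alpha0)` (any ordering; reordered internally).
#' @param alpha overall FWER level in (0, 1).
#' @param validate check regularity (default `TRUE`).
#' @return object of class `weighted_test_graph`.
#' @examples
#' # the Holm procedure on three hypotheses
#' g <- holm_graph(c("a", "b", "c"), alpha = 0.05)
#' sequential_reject(g, c(a = 0.001, b = 0.02, c = 0.9))$rejected
#' @export
weighted_test_graph <- function(alpha0, G, alpha = 0.05, validate = TRUE) {
  hyp <- names(alpha0)
  if (is.null(hyp) || anyDuplicated(hyp))
    stop("'alpha0' must have unique names")
  if (!is.matrix(G) || nrow(G) != length(hyp) || ncol(G) != length(hyp))
    stop("'G' must be a square matrix matching 'alpha0'")
  if (is.null(dimnames(G))) dimnames(G) <- list(hyp, hyp)
  G <- G[hyp, hyp, drop = FALSE]
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  x <- structure(list(hypotheses = hyp, alpha0 = alpha0, G = G, alpha = alpha),
                 class = "weighted_test_graph")
  if (validate) {
    v <- validate_regularity(x)
    if (!v$ok) stop("invalid weighted test graph: ",
                    paste(v$violations, collapse = "; "))
  }
  x
}

#' The complete symmetric (Holm) test graph
#'
#' Local thresholds `alpha/m` with every pair of hypotheses joined by
#' edges of weight `1/(m-1)`; running [sequential_reject()] on this graph
#' reproduces the Holm step-down procedure.
#'
#' @param hypotheses character vector of hypothesis names.
#' @param alpha overall level.
#' @export
holm_graph <- function(hypotheses, alpha = 0.05) {
  m <- length(hypotheses)
  G <- if (m > 1L) matrix(1 / (m - 1), m, m) - diag(1 / (m - 1), m)
       else matrix(0, 1L, 1L)
  dimnames(G) <- list(hypotheses, hypotheses)
  weighted_test_graph(setNames(rep(alpha / m, m), hypotheses), G, alpha)
}

#' Check the regularity conditions of a weighted test graph
#'
#' Condition 1: the local thresholds sum to at most the overall level.
#' Condition 2: all edge weights lie in `[0, 1]`, the diagonal is zero,
#' and every row of `G` sums to at most 1.  Sums are checked with
#' tolerance `1e-12`.
#'
#' @param graph a [weighted_test_graph()] (built with `validate = FALSE`
#'   if you expect it to fail).
#' @param tol numerical tolerance on the sum constraints.
#' @return list with `ok` (logical) and `violations` (character vector
#'   describing each failed condition).
#' @export
validate_regularity <- function(graph, tol = 1e-12) {
  a <- graph$alpha0; G <- graph$G
  bad <- character(0)
  if (any(a < -tol)) bad <- c(bad, "condition 1: negative local threshold")
  if (sum(a) > graph$alpha + tol)
    bad <- c(bad, sprintf("condition 1: sum of local thresholds %.6g exceeds alpha = %.6g",
                          sum(a), graph$alpha))
  if (any(G < -tol | G > 1 + tol))
    bad <- c(bad, "condition 2: edge weight outside [0, 1]")
  if (any(abs(diag(G)) > tol))
    bad <- c(bad, paste0("condition 2: nonzero diagonal weight g_ii at ",
                         paste(graph$hypotheses[abs(diag(G)) > tol], collapse = ", ")))
  rs <- rowSums(G)
  if (any(rs > 1 + tol))
    bad <- c(bad, paste0("condition 2: row sum exceeds 1 at ",
                         paste(graph$hypotheses[rs > 1 + tol], collapse = ", ")))
  list(ok = !length(bad), violations = bad)
}

#' @export
print.weighted_test_graph <- function(x, ...) {
  cat("weighted_test_graph:", length(x$hypotheses),
      "hypotheses, alpha =", x$alpha, "\n")
  cat("  positive thresholds:", sum(x$alpha0 > 0), "; edges:",
      sum(x$G > 0), "\n")
  invisible(x)
}

#' Start a sequential rejection state
#'
#' @param graph a [weighted_test_graph()].
#' @return object of class `sequential_state`: current thresholds `alpha`,
#'   weights `G`, logical `active` marker, cumulative rejection set
#'   `rejected` (in rejection order) and an audit `log` data frame of
#'   threshold flows.
#' @export
new_sequential_state <- function(graph) {
  structure(list(
    hypotheses = graph$hypotheses,
    alpha = graph$alpha0,
    G = graph$G,
    alpha_total = graph$alpha,
    active = setNames(rep(TRUE, length(graph$hypotheses)), graph$hypotheses),
    rejected = character(0),
    log = data.frame(step = integer(0), rejected = character(0),
                     threshold = numeric(0), mass_recycled = numeric(0),
                     stringsAsFactors = FALSE)
  ), class = "sequential_state")
}

#' Reject one hypothesis and update the graph
#'
#' Applies the standard graphical update: the rejected hypothesis `j`
#' passes the share `g_jl` of its local threshold to every still-active
#' hypothesis `l`, and edge weights are rewired as
#' `g_lk <- (g_lk + g_lj g_jk) / (1 - g_lj g_jl)` (set to 0 when the
#' denominator is nonpositive).  Threshold mass routed to `j` itself or to
#' hypotheses with no incoming path is lost, never created, so the sum of
#' active thresholds can only stay equal or shrink.
#'
#' @param state a [new_sequential_state()] object.
#' @param j the hypothesis to reject (must be active).
#' @return the updated `sequential_state`.
#' @export
reject_update <- function(state, j) {
  if (!j %in% state$hypotheses) stop("unknown hypothesis: ", j)
  if (!state$active[j]) stop("hypothesis already rejected: ", j)
  act <- state$active & state$hypotheses != j
  aj <- state$alpha[j]
  gj <- state$G[j, ]              # outgoing shares of j
  recycled <- aj * sum(gj[act])
  state$alpha[act] <- state$alpha[act] + aj * gj[act]
  state$alpha[j] <- 0

  if (any(act)) {
    A <- which(act)
    Gn <- state$G
    gin <- state$G[, j]           # incoming weights l -> j
    # g_lk update, vectorised over the active block
    num <- state$G[A, A, drop = FALSE] + gin[A] %o% gj[A]
    den <- 1 - gin[A] * gj[A]     # per-row denominator 1 - g_lj g_jl
    new <- num / ifelse(den > 1e-15, den, Inf)
    new[den <= 1e-15, ] <- 0
    diag(new) <- 0
    Gn[A, A] <- new
    Gn[j, ] <- 0
    Gn[, j] <- 0
    state$G <- Gn
  } else {
    state$G[j, ] <- 0
    state$G[, j] <- 0
  }
  state$active[j] <- FALSE
  state$rejected <- c(state$rejected, j)
  state$log <- rbind(state$log, data.frame(
    step = length(state$rejected), rejected = j, threshold = aj,
    mass_recycled = recycled, stringsAsFactors = FALSE))
  state
}

#' Graphical sequentially rejective multiple test
#'
#' Repeatedly rejects any eligible hypothesis whose p-value does not
#' exceed its current local threshold, applying [reject_update()] after
#' each rejection, until no hypothesis qualifies.  A level-zero local test
#' never rejects (thresholds of 0 are inert).  With the default
#' always-eligible predicate this is the unrestricted graphical
#' Bonferroni procedure; restricted families supply `eligible` to keep a
#' hypothesis untestable until the hypotheses implying it are rejected
#' (threshold mass reaching an ineligible hypothesis accumulates --
#' escrow -- and becomes usable the moment it turns eligible).
#'
#' The rejection order uses the smallest ratio `p/alpha_i` (then
#' lexicographic name) purely so that audit logs are reproducible; the
#' final rejection set is order-invariant.
#'
#' @param graph a [weighted_test_graph()].
#' @param p named p-value vector covering all hypotheses.
#' @param eligible `NULL`, or `function(hypothesis, state)` returning
#'   `TRUE` when the hypothesis may be tested.
#' @param tol boundary slack for `p <= alpha_i` comparisons.
#' @return the final `sequential_state`; element `rejected` is the
#'   cumulative rejection set.
#' @export
sequential_reject <- function(graph, p, eligible = NULL, tol = 1e-12) {
  if (is.null(names(p))) stop("'p' must be named")
  missing <- setdiff(graph$hypotheses, names(p))
  if (length(missing)) stop("missing p-values for: ", paste(missing, collapse = ", "))
  p <- p[graph$hypotheses]
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  state <- new_sequential_state(graph)
  repeat {
    ok <- state$active & state$alpha > 0 & p <= state$alpha + tol
    if (!is.null(eligible) && any(ok))
      for (h in names(ok)[ok]) ok[h] <- isTRUE(eligible(h, state))
    if (!any(ok)) break
    cand <- names(ok)[ok]
    ratio <- p[cand] / state$alpha[cand]
    j <- cand[order(ratio, cand)][1]
    state <- reject_update(state, j)
  }
  state
}

#' Restricted sequentially rejective shortcut (at most m stages)
#'
#' The graphical shortcut extended to logically restricted hypothesis
#' families.  At each stage, with `M` the set of not-yet-rejected
#' hypotheses, the current global intersection hypothesis `H_M` is tested
#' through its canonical minimal representation: `I` is the
#' minimum-cardinality subcollection of the *maximal* members of `M`
#' whose evidence union equals that of `M` (lexicographic tie-break), and
#' `H_M = H_I` is rejected -- together with one elementary hypothesis --
#' as soon as some `j` in `I` satisfies `p_j <= alpha_j(I)`, where the
#' local levels `alpha_j(I)` are obtained from the graph by removing
#' every hypothesis outside `I` via the rejection-update rule (see
#' [bretz_local_levels()]).  The rejected `j` leaves `M` and the stage
#' repeats, for at most `m` stages.
#'
#' Because `I` contains only maximal unrejected hypotheses, an elementary
#' hypothesis is never tested before everything implying it has been
#' rejected; and because the levels of the minimal representation recycle
#' the threshold mass of all hypotheses outside `I`, the procedure
#' reproduces the rejections of the brute-force restricted closed test
#' (asserted against [closed_test_oracle()] in the test suite).  For an
#' unrestricted family every member is maximal and `I = M`, recovering
#' the plain graphical procedure.
#'
#' @param graph a [weighted_test_graph()].
#' @param family a [hypothesis_family()] over the same hypotheses.
#' @param p named p-values.
#' @param alpha level at which to test; defaults to the graph's overall
#'   level.  Levels scale linearly, so other values re-use the same graph.
#' @param cache optional environment carrying memoised level weights
#'   across calls with the same graph (used by adjusted p-value
#'   bisection).
#' @param tol boundary slack for `p <= alpha_j(I)`.
#' @return list with `rejected` (in rejection order) and `stages` (data
#'   frame audit trail: stage, tested index set, rejected hypothesis and
#'   its local level).
#' @export
restricted_sequential <- function(graph, family, p, alpha = graph$alpha,
                                  cache = NULL, tol = 1e-12) {
  stopifnot(inherits(graph, "weighted_test_graph"),
            inherits(family, "hypothesis_family"))
  if (!setequal(graph$hypotheses, family$hypotheses))
    stop("graph and family must index the same hypotheses")
  p <- p[family$hypotheses]
  if (any(is.na(p))) stop("missing p-values")
  if (is.null(cache)) cache <- new.env(hash = TRUE, parent = emptyenv())
  ev <- family$evidence

  level_weights <- function(I) {
    key <- paste0("w:", paste(I, collapse = "\r"))
    w <- cache[[key]]
    if (is.null(w)) {
      w <- bretz_local_levels(graph, I) / graph$alpha
      cache[[key]] <- w
    }
    w
  }
  cover_of <- function(M) {
    key <- paste0("c:", paste(sort(M), collapse = "\r"))
    I <- cache[[key]]
    if (is.null(I)) {
      target <- unique(unlist(ev[M], use.names = FALSE))
      I <- min_cover_index(ev[M], target)
      cache[[key]] <- I
    }
    I
  }

  M <- sort(family$hypotheses)
  S <- character(0)
  stages <- list()
  while (length(M)) {
    I <- cover_of(M)
    lev <- alpha * level_weights(I)
    ok <- lev > 0 & p[I] <= lev + tol
    if (!any(ok)) break
    cand <- I[ok]
    j <- cand[order(p[cand] / lev[cand], cand)][1]
    stages[[length(stages) + 1L]] <- data.frame(
      stage = length(S) + 1L, index_set = paste(I, collapse = ","),
      rejected = j, level = lev[j], stringsAsFactors = FALSE)
    S <- c(S, j)
    M <- setdiff(M, j)
  }
  list(rejected = S,
       stages = if (length(stages)) do.call(rbind, stages)
                else data.frame(stage = integer(0), index_set = character(0),
                                rejected = character(0), level = numeric(0)))
}
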