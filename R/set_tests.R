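#' Expression study container
#'
#' A samples-by-genes expression matrix (real-valued or counts) together
#' with a phenotype vector: continuous, or two-group coded as a factor or
#' 0/1.
#'
#' @param X numeric matrix, samples in rows, genes in columns; column
#'   names are gene identifiers.
#' @param y phenotype of length `nrow(X)`.
#' @return object of class `expression_study` with elements `X`, `y`,
#'   `n`, `m_genes`.
#' @export
expression_study <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("'X' must have gene identifiers as colnames")
  if (is.factor(y)) {
    if (nlevels(droplevels(y)) != 2L) stop("factor phenotype must have 2 levels")
    y <- as.numeric(droplevels(y)) - 1
  }
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  structure(list(X = X, y = y, n = nrow(X), m_genes = ncol(X)),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", x$n, "samples x", x$m_genes, "genes\n")
  invisible(x)
}

clip_pvalues <- function(p, lo = 1e-15) {
  if (any(p <= 0 | p >= 1)) {
    warning("p-values of exactly 0 or 1 clipped to [1e-15, 1 - 1e-15]")
    p <- pmin(pmax(p, lo), 1 - lo)
  }
  p
}

#' Stouffer p-value combination
#'
#' Transforms each per-gene p-value to a standard normal Z-score
#' (upper-tail quantile) and refers the combined score to the standard
#' normal upper tail.  The default combines as `sum(Z) / sqrt(k)`, which
#' is uniform under the null of k independent uniform p-values.  The
#' `"mean"` variant uses the unscaled mean Z-score instead; it is *not*
#' null-uniform and exists only for fidelity experiments with tools that
#' combine that way.
#'
#' Inputs are assumed to be one-sided p-values in a common direction;
#' two-sided p-values must be split by direction upstream.
#'
#' @param p numeric vector of per-gene p-values in (0, 1); values of
#'   exactly 0 or 1 are clipped to `1e-15` from the boundary with a
#'   warning.
#' @param method `"sqrt_k"` (default) or `"mean"`.
#' @return single combined p-value.
#' @examples
#' stouffer_combine(c(0.05, 0.05))  # 0.0100
#' @export
stouffer_combine <- function(p, method = c("sqrt_k", "mean")) {
  method <- match.arg(method)
  if (!length(p)) stop("need at least one p-value")
  p <- clip_pvalues(p)
  z <- qnorm(p, lower.tail = FALSE)
  stat <- if (method == "sqrt_k") sum(z) / sqrt(length(z)) else mean(z)
  pnorm(stat, lower.tail = FALSE)
}

#' Fisher p-value combination
#'
#' Refers `-2 * sum(log(p))` to the chi-square distribution with `2k`
#' degrees of freedom, upper tail.
#'
#' @inheritParams stouffer_combine
#' @return single combined p-value.
#' @export
fisher_combine <- function(p) {
  if (!length(p)) stop("need at least one p-value")
  p <- clip_pvalues(p)
  pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

# Exact first two moments of Q(pi) = y[pi]' A y[pi] under uniformly random
# permutations pi, for symmetric A.  Computed by classifying the index
# tuples of E[Q^2] = sum_{ijkl} A_ij A_kl E[y_pi(i) y_pi(j) y_pi(k) y_pi(l)]
# by their equality pattern (the 15 set partitions of four slots), with
# exact-pattern sums obtained from collapsed sums by Moebius inversion on
# the partition lattice.  Verified in the test suite against exhaustive
# enumeration of all permutations at small n.
perm_quadform_moments <- function(A, y) {
  n <- length(y)
  stopifnot(is.matrix(A), nrow(A) == n, ncol(A) == n)
  if (max(abs(A - t(A))) > 1e-8 * (1 + max(abs(A)))) stop("'A' must be symmetric")
  A <- (A + t(A)) / 2
  r <- rowSums(A)
  Tr <- sum(diag(A)); S <- sum(A)
  F2 <- sum(A * A); DR <- sum(diag(A) * r); D2 <- sum(diag(A)^2)
  R2 <- sum(r^2)

  ps <- vapply(1:4, function(k) sum(y^k), 0)  # power sums p1..p4
  # sum over *distinct* position tuples of prod y^e
  Dy <- function(e) {
    if (length(e) == 1L) return(ps[e])
    g <- length(e)
    val <- Dy(e[-g]) * ps[e[g]]
    for (j in seq_len(g - 1L)) {
      em <- e[-g]; em[j] <- em[j] + e[g]
      val <- val - Dy(em)
    }
    val
  }
  falling <- function(n, g) prod(n - 0:(g - 1))

  # E[Q]
  EQ <- Tr * ps[2] / n + (S - Tr) * (ps[1]^2 - ps[2]) / (n * (n - 1))

  # partitions of the four slots (i, j) x (k, l), as label vectors
  parts <- list(
    c(1, 2, 3, 4),
    c(1, 1, 2, 3), c(1, 2, 1, 3), c(1, 2, 3, 1),
    c(1, 2, 2, 3), c(1, 2, 3, 2), c(1, 2, 3, 3),
    c(1, 1, 2, 2), c(1, 2, 1, 2), c(1, 2, 2, 1),
    c(1, 1, 1, 2), c(1, 1, 2, 1), c(1, 2, 1, 1), c(1, 2, 2, 2),
    c(1, 1, 1, 1))
  collapsed <- c(
    S^2,
    Tr * S, R2, R2,
    R2, R2, Tr * S,
    Tr^2, F2, F2,
    DR, DR, DR, DR,
    D2)
  ngroups <- vapply(parts, function(p) length(unique(p)), 1L)
  refines <- function(p, q) {  # p finer than q: p's equalities subset of q's
    for (s in 1:3) for (t in (s + 1):4)
      if (p[s] == p[t] && q[s] != q[t]) return(FALSE)
    TRUE
  }
  exact <- numeric(15)
  ord <- order(ngroups)  # coarsest (fewest groups) first
  for (i in ord) {
    val <- collapsed[i]
    for (j in seq_len(15)) if (j != i && ngroups[j] < ngroups[i] &&
                               refines(parts[[i]], parts[[j]]))
      val <- val - exact[j]
    exact[i] <- val
  }
  EQ2 <- 0
  for (i in seq_len(15)) {
    if (exact[i] == 0) next
    sizes <- as.integer(table(parts[[i]]))
    EQ2 <- EQ2 + exact[i] * Dy(sizes) / falling(n, ngroups[i])
  }
  list(mean = EQ, var = EQ2 - EQ^2)
}

#' Global score test for association of a gene set with a phenotype
#'
#' Tests the self-contained null that no gene in the set is associated
#' with the phenotype, using the quadratic-form score statistic
#' `Q = (y - ybar)' R (y - ybar)` with `R = X_S X_S' / |S|` on the
#' column-centred expression submatrix of the set.  Large `Q` indicates
#' that the phenotype varies along directions of expression space spanned
#' by the set.
#'
#' The `"asymptotic"` method refers `Q` to a moment-matched scaled
#' chi-square (gamma) distribution whose first two moments are computed
#' exactly under the permutation null of the phenotype; the
#' `"permutation"` method uses `n_perm` random phenotype permutations
#' with the add-one correction `(b + 1) / (n_perm + 1)`.
#'
#' @param study an [expression_study()].
#' @param geneset character vector of gene identifiers (default: all
#'   genes in the study); genes absent from the study are ignored, an
#'   empty intersection is an error.
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm number of permutations for `method = "permutation"`.
#' @param seed optional seed for the permutation draw.
#' @return single p-value.
#' @export
global_test <- function(study, geneset = NULL,
                        method = c("asymptotic", "permutation"),
                        n_perm = 1000L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(study, "expression_study"))
  if (study$n < 3L) stop("need at least 3 samples")
  y <- study$y
  if (var(y) == 0) stop("phenotype 'y' is constant; association undefined")
  genes <- if (is.null(geneset)) colnames(study$X)
           else intersect(as.character(geneset), colnames(study$X))
  if (!length(genes)) stop("gene set has empty intersection with the study")
  Xs <- study$X[, genes, drop = FALSE]
  Xs <- sweep(Xs, 2L, colMeans(Xs))
  k <- length(genes)
  yc <- y - mean(y)
  Zt <- crossprod(Xs, yc)                      # |S| x 1
  Q <- sum(Zt^2) / k

  if (method == "asymptotic") {
    R <- tcrossprod(Xs) / k
    mom <- perm_quadform_moments(R, yc)
    if (mom$mean <= 0 || mom$var <= 0) return(1)
    shape <- mom$mean^2 / mom$var
    scale <- mom$var / mom$mean
    pgamma(Q, shape = shape, scale = scale, lower.tail = FALSE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    B <- as.integer(n_perm)
    P <- vapply(seq_len(B), function(b) yc[sample.int(study$n)],
                numeric(study$n))
    Qb <- colSums(crossprod(Xs, P)^2) / k
    (1 + sum(Qb >= Q - 1e-12)) / (B + 1)
  }
}

#' Per-term gene-set p-values from per-gene p-values
#'
#' Convenience wrapper applying a p-value combiner to every term of a
#' gene-set DAG.
#'
#' @param dag a `gene_set_dag`.
#' @param gene_p named vector of per-gene p-values.
#' @param combiner `"stouffer"` or `"fisher"`.
#' @return named vector of per-term p-values.
#' @export
combine_by_term <- function(dag, gene_p, combiner = c("stouffer", "fisher")) {
  combiner <- match.arg(combiner)
  f <- if (combiner == "stouffer") stouffer_combine else fisher_combine
  out <- vapply(dag$terms, function(t) {
    g <- intersect(dag$membership[[t]], names(gene_p))
    if (!length(g)) stop("term '", t, "' has no genes with p-values")
    f(gene_p[g])
  }, 0)
  setNames(out, dag$terms)
}
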