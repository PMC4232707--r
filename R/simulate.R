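#' The fixed 14-term gene-set system of the Gaussian power study
#'
#' One hundred genes partitioned among 14 nested GO-style identifiers:
#' a root covering all genes, three mid-level terms, and ten more specific
#' terms, with overlaps chosen so that several mid-level terms are exact
#' unions of their children.  Used by [simulate_sim2()].
#'
#' @return named list of gene identifier vectors (genes `g001`..`g100`).
#' @export
sim2_genesets <- function() {
  g <- function(i) sprintf("g%03d", i)
  list(
    "GO:01" = g(1:100), "GO:02" = g(1:40),  "GO:03" = g(21:60),
    "GO:04" = g(61:100), "GO:05" = g(1:10),  "GO:06" = g(11:20),
    "GO:07" = g(21:40), "GO:08" = g(41:50), "GO:09" = g(51:60),
    "GO:10" = g(61:80), "GO:11" = g(71:90), "GO:12" = g(81:100),
    "GO:13" = g(72:79), "GO:14" = g(82:89))
}

#' @rdname sim2_genesets
#' @export
sim2_dag <- function() infer_hasse(sim2_genesets())

sim2_signal_sets <- c("GO:06", "GO:07", "GO:13")
sim2_truth <- c("GO:01", "GO:02", "GO:03", "GO:04", "GO:06", "GO:07",
                "GO:10", "GO:11", "GO:13")

#' Simulate a Gaussian expression study with a continuous phenotype
#'
#' Generates the second simulation design: a phenotype `Y ~ N(0, 1)` of
#' length `n` and an `n x 100` matrix of independent `N(0, 1)` expression
#' values on the gene sets of [sim2_genesets()].  The gene sets GO:06,
#' GO:07 and GO:13 carry signal: `r * Y` is added to the expression of
#' their genes, so every set containing one of them (GO:01--GO:04, GO:10,
#' GO:11) is also truly associated with the phenotype by inheritance.
#' `r = 0` gives a complete null.
#'
#' @param n number of samples (default 20).
#' @param r effect size in `[0, 1]` (default 0.5).
#' @param seed optional seed.
#' @return list with `study` (an [expression_study()]), `dag` (the Hasse
#'   DAG of the 14 sets), `truth` (character vector of truly associated
#'   terms), `signal_sets`.
#' @export
simulate_sim2 <- function(n = 20L, r = 0.5, seed = NULL) {
  stopifnot(r >= 0, r <= 1, n >= 3L)
  if (!is.null(seed)) set.seed(seed)
  sets <- sim2_genesets()
  genes <- sprintf("g%03d", 1:100)
  y <- rnorm(n)
  X <- matrix(rnorm(n * 100L), n, 100L, dimnames = list(NULL, genes))
  if (r > 0) {
    sig <- unique(unlist(sets[sim2_signal_sets], use.names = FALSE))
    X[, sig] <- X[, sig] + r * y
  }
  list(study = expression_study(X, y), dag = infer_hasse(sets),
       truth = if (r > 0) sim2_truth else character(0),
       signal_sets = sim2_signal_sets)
}

default_mean_sampler <- function(k) exp(rnorm(k, 3.0, 1.5))

#' Simulate an RNA-seq counts study on a random nested gene-set graph
#'
#' Generates the first simulation design: a two-group RNA-seq counts
#' study on the six-term nested topology `A -> {B, F}`, `B -> {C, D, E}`,
#' `F -> E` (root A; leaves C, D, E).  Genes are first assigned to the
#' leaf sets (sizes uniform on `1..max_size`) with overlap between `j`
#' leaf sets occurring with probability proportional to `2^-j`, so
#' many-way sharing is rare; parents then receive fresh genes plus all
#' genes of their children, producing the nested overlap structure of
#' real ontologies.
#'
#' Counts for the control group are negative binomial with mean `mu_i`
#' (drawn from `mean_sampler`) and variance `mu_i + mu_i^2 / d`.  Each
#' leaf set is independently selected to carry signal with probability
#' `prob_sig`; genes of selected leaves get treatment means
#' `2^beta_i * mu_i` with `beta_i ~ Poisson(lambda)` (so some genes of a
#' significant set may still have zero effect).  Group sizes are
#' `Binomial(n, 0.5)`, redrawn until both groups have at least two
#' samples.  A term is truly differentially expressed iff it contains at
#' least one gene with `beta_i > 0`.
#'
#' @param n total number of samples (>= 4).
#' @param max_size maximum leaf-set size (10 or 40 in the study design).
#' @param lambda Poisson rate of per-gene log2 effect sizes (0--3).
#' @param d negative binomial scaling parameter (variance
#'   `mu + mu^2/d`), default 10.
#' @param prob_sig probability a leaf set carries signal, default 0.5.
#' @param mean_sampler function of `k` returning `k` control means; the
#'   default draws log-normal means (log-mean 3, log-sd 1.5, median about
#'   20 counts) as a stand-in for means resampled from a real data set.
#' @param seed optional seed.
#' @return list with `study` (counts [expression_study()], `y` is 0/1
#'   group), `dag`, `truth`, `beta` (named per-gene log2 effects).
#' @export
simulate_sim1 <- function(n = 20L, max_size = 10L, lambda = 1, d = 10,
                          prob_sig = 0.5, mean_sampler = default_mean_sampler,
                          seed = NULL) {
  stopifnot(n >= 4L, max_size >= 1L, lambda >= 0, d > 0)
  if (!is.null(seed)) set.seed(seed)

  leaves <- c("C", "D", "E")
  sizes <- setNames(sample.int(max_size, 3L, replace = TRUE), leaves)
  membership <- setNames(vector("list", 3L), leaves)
  next_gene <- 0L
  new_genes <- function(k) {
    out <- sprintf("g%04d", next_gene + seq_len(k))
    next_gene <<- next_gene + k
    out
  }
  # fill leaf sets gene by gene; each gene joins j leaves with P ~ 2^-j
  repeat {
    open <- leaves[vapply(membership, length, 1L) < sizes]
    if (!length(open)) break
    jmax <- length(open)
    pj <- 2^-(seq_len(jmax)); pj <- pj / sum(pj)
    j <- sample.int(jmax, 1L, prob = pj)
    to <- if (jmax == 1L) open else sample(open, j)
    gid <- new_genes(1L)
    for (t in to) membership[[t]] <- c(membership[[t]], gid)
  }
  membership$B <- c(new_genes(sample.int(max_size, 1L)),
                    unlist(membership[c("C", "D", "E")], use.names = FALSE))
  membership$F <- c(new_genes(sample.int(max_size, 1L)), membership$E)
  membership$A <- c(new_genes(sample.int(max_size, 1L)),
                    membership$B, membership$F)
  membership <- lapply(membership, function(g) sort(unique(g)))
  edges <- data.frame(
    parent = c("A", "A", "B", "B", "B", "F"),
    child  = c("B", "F", "C", "D", "E", "E"), stringsAsFactors = FALSE)
  dag <- build_dag(edges, membership)

  genes <- sort(unique(unlist(membership, use.names = FALSE)))
  m <- length(genes)
  mu <- setNames(mean_sampler(m), genes)

  sig_leaves <- leaves[runif(3L) < prob_sig]
  beta <- setNames(rep(0, m), genes)
  sig_genes <- unique(unlist(membership[sig_leaves], use.names = FALSE))
  if (length(sig_genes)) beta[sig_genes] <- rpois(length(sig_genes), lambda)

  repeat {
    n_trt <- rbinom(1L, n, 0.5)
    if (n_trt >= 2L && n - n_trt >= 2L) break
  }
  y <- c(rep(0L, n - n_trt), rep(1L, n_trt))
  mu_trt <- mu * 2^beta
  X <- matrix(0L, n, m, dimnames = list(NULL, genes))
  ctrl <- y == 0L
  X[ctrl, ]  <- matrix(rnbinom((n - n_trt) * m, mu = rep(mu, each = n - n_trt),
                               size = d), n - n_trt, m)
  X[!ctrl, ] <- matrix(rnbinom(n_trt * m, mu = rep(mu_trt, each = n_trt),
                               size = d), n_trt, m)

  truth <- dag$terms[vapply(dag$terms, function(t)
    any(beta[dag$membership[[t]]] > 0), TRUE)]
  list(study = expression_study(X, y), dag = dag, truth = truth, beta = beta)
}

#' Monte Carlo power and FWER harness
#'
#' Repeats: generate a study, compute per-term p-values with a
#' self-contained set test, run a multiplicity procedure, and record the
#' rejections.  Reports per-term empirical rejection frequency (power for
#' truly associated terms) with Monte Carlo standard errors, and the
#' familywise error rate estimate: the fraction of replicates rejecting
#' at least one truly null term.
#'
#' Each replicate runs under its own seed derived from `seed`, so results
#' are reproducible and independent of evaluation order.
#'
#' @param generator function of a single `seed` argument returning a list
#'   with `study`, `dag`, `truth` (see [simulate_sim2()]).
#' @param set_test function `(study, genes)` returning one p-value;
#'   default wraps [global_test()].
#' @param procedure function `(dag, p, alpha)` returning the character
#'   vector of rejected terms; default is [sfl()] with root focus.
#' @param n_reps number of Monte Carlo replicates.
#' @param alpha FWER level.
#' @param seed master seed.
#' @return list with `per_term` (data frame `term`, `truth`, `power`,
#'   `mc_se`), `fwer`, `fwer_se`, `n_reps`, `alpha`.
#' @export
power_harness <- function(generator,
                          set_test = function(study, genes)
                            global_test(study, genes),
                          procedure = function(dag, p, alpha) {
                            res <- sfl(dag, p, focus = "root", alpha = alpha,
                                       min_set_size = 0L, adjusted = FALSE)
                            res$term[res$rejected]
                          },
                          n_reps = 100L, alpha = 0.05, seed = 1L) {
  stopifnot(n_reps >= 1L)
  rej_count <- NULL
  truth_tab <- NULL
  fwer_hits <- 0L
  for (b in seq_len(n_reps)) {
    sim <- generator(seed + b)
    p <- vapply(sim$dag$terms, function(t)
      set_test(sim$study, sim$dag$membership[[t]]), 0)
    names(p) <- sim$dag$terms
    rej <- procedure(sim$dag, p, alpha)
    if (is.null(rej_count)) {
      rej_count <- setNames(rep(0L, sim$dag$m), sim$dag$terms)
      truth_tab <- setNames(rep(0L, sim$dag$m), sim$dag$terms)
    }
    rej_count[rej] <- rej_count[rej] + 1L
    truth_tab[sim$truth] <- truth_tab[sim$truth] + 1L
    nulls <- setdiff(sim$dag$terms, sim$truth)
    if (any(rej %in% nulls)) fwer_hits <- fwer_hits + 1L
  }
  pw <- rej_count / n_reps
  fwer <- fwer_hits / n_reps
  list(per_term = data.frame(
         term = names(pw),
         truth = unname(truth_tab / n_reps),
         power = unname(pw),
         mc_se = unname(sqrt(pw * (1 - pw) / n_reps)),
         stringsAsFactors = FALSE, row.names = NULL),
       fwer = fwer,
       fwer_se = sqrt(fwer * (1 - fwer) / n_reps),
       n_reps = n_reps, alpha = alpha)
}
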