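# Shared fixtures, all built in code.

# Six-term toy DAG (root A; B and F intermediate; leaves C, D, E with
# E below both B and F), in generic position: every term keeps at least
# one gene absent from all other terms.
toy_membership <- function() {
  list(A = c("a", "b", "c", "d", "e", "f"),
       B = c("b", "c", "d", "e"),
       F = c("e", "f"),
       C = "c", D = "d", E = "e")
}

toy_edges <- function() {
  data.frame(parent = c("A", "A", "B", "B", "B", "F"),
             child  = c("B", "F", "C", "D", "E", "E"),
             stringsAsFactors = FALSE)
}

toy_dag <- function() build_dag(toy_edges(), toy_membership())

# Partially nested abstract family: H1 implies H2, H3 implies H4
# (stricter one-sided nulls imply the weaker), encoded with tokens.
nested4_family <- function() {
  hypothesis_family(list(H1 = c("a1", "a2"), H2 = "a1",
                         H3 = c("b1", "b2"), H4 = "b1"))
}

# The cyclic test graph performing the closed test of the partially
# nested family: mass alpha/2 on the stricter hypotheses, each pointing
# to the hypothesis it implies, which points on to the other branch.
nested4_graph <- function(alpha = 0.05) {
  h <- c("H1", "H2", "H3", "H4")
  G <- matrix(0, 4, 4, dimnames = list(h, h))
  G["H1", "H2"] <- 1; G["H2", "H3"] <- 1
  G["H3", "H4"] <- 1; G["H4", "H1"] <- 1
  weighted_test_graph(c(H1 = alpha / 2, H2 = 0, H3 = alpha / 2, H4 = 0),
                      G, alpha)
}

# Random nested gene-set DAG in generic position: random subsets of a
# small gene universe plus one private gene per term and a root over
# everything.
random_generic_dag <- function(m_max = 7, n_genes = 8) {
  repeat {
    m <- sample(3:m_max, 1)
    genes <- paste0("g", seq_len(n_genes))
    mem <- list()
    for (i in seq_len(m - 1))
      mem[[paste0("t", i)]] <- unique(c(
        sample(genes, sample.int(n_genes, 1)), paste0("priv", i)))
    mem[["root"]] <- unique(c(genes, paste0("priv", seq_len(m - 1)), "privroot"))
    sig <- vapply(mem, function(s) paste(sort(s), collapse = ","), "")
    if (!anyDuplicated(sig)) return(infer_hasse(mem))
  }
}

# Random nested DAG without the generic-position guarantee (terms may be
# exact unions of others), for conservativeness checks.
random_nested_dag <- function(m_max = 7, n_genes = 10) {
  repeat {
    m <- sample(3:m_max, 1)
    genes <- paste0("g", seq_len(n_genes))
    mem <- list()
    for (i in seq_len(m - 1))
      mem[[paste0("t", i)]] <- sample(genes, sample.int(n_genes - 1, 1))
    mem[["root"]] <- genes
    sig <- vapply(mem, function(s) paste(sort(s), collapse = ","), "")
    if (!anyDuplicated(sig)) return(infer_hasse(mem))
  }
}
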