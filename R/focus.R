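#' Validate a focus level and stratify the DAG
#'
#' A *focus level* is a set `F` of terms at which testing effort is
#' concentrated.  It must satisfy two rules:
#' \describe{
#'   \item{FL1}{no element of `F` is an offspring of another element of
#'     `F` (the focus level is an antichain);}
#'   \item{FL2}{every term not in `F` is an ancestor or an offspring of
#'     some focus term, so the three strata cover the graph.}
#' }
#' On success every term is assigned one of the strata `"ancestor"`,
#' `"focus"`, `"offspring"`.  Violations raise classed errors
#' (`sfl_fl1_error`, `sfl_fl2_error`) whose message names the offending
#' terms.
#'
#' @param dag a [build_dag()] object.
#' @param F character vector of focus term identifiers, or the string
#'   `"root"` to select all parentless terms (the full top-down choice).
#' @return an object of class `focus_level`: list with `terms` (the focus
#'   set, sorted), `m_F`, and `strata` (named character vector over all
#'   DAG terms).
#' @examples
#' dag <- infer_hasse(list(A = c("g1", "g2"), B = "g1", C = "g2"))
#' fl <- validate_focus_level(dag, "root")
#' fl$strata
#' @export
validate_focus_level <- function(dag, F) {
  stopifnot(inherits(dag, "gene_set_dag"))
  if (identical(F, "root"))
    F <- dag$terms[vapply(dag$parents, length, 1L) == 0L]
  F <- sort(unique(as.character(F)))
  if (!length(F)) stop("focus level must contain at least one term")
  unknown <- setdiff(F, dag$terms)
  if (length(unknown)) stop("unknown focus term(s): ", paste(unknown, collapse = ", "))

  # FL1: focus terms must not be offspring of focus terms
  for (f in F) {
    bad <- intersect(dag$offspring[[f]], F)
    if (length(bad))
      stop(structure(class = c("sfl_fl1_error", "error", "condition"),
        list(message = paste0("FL1 violation: focus term '", bad[1],
               "' is an offspring of focus term '", f, "'"),
             call = sys.call(-1), terms = c(f, bad[1]))))
  }
  strata <- setNames(rep(NA_character_, dag$m), dag$terms)
  strata[F] <- "focus"
  anc <- unique(unlist(dag$ancestors[F], use.names = FALSE))
  off <- unique(unlist(dag$offspring[F], use.names = FALSE))
  strata[setdiff(off, F)] <- "offspring"
  strata[setdiff(anc, c(F, off))] <- "ancestor"
  uncovered <- dag$terms[is.na(strata)]
  if (length(uncovered))
    stop(structure(class = c("sfl_fl2_error", "error", "condition"),
      list(message = paste0("FL2 violation: term(s) neither ancestor nor ",
             "offspring of the focus level: ", paste(uncovered, collapse = ", ")),
           call = sys.call(-1), terms = uncovered)))

  structure(list(terms = F, m_F = length(F), strata = strata),
            class = "focus_level")
}

#' @export
print.focus_level <- function(x, ...) {
  cat("focus_level:", x$m_F, "focus term(s);",
      sum(x$strata == "ancestor"), "ancestor,",
      sum(x$strata == "offspring"), "offspring term(s)\n")
  invisible(x)
}

#' Automatic focus-level selection (not implemented)
#'
#' The original Focus Level machinery recommends choosing the focus level
#' so that the offspring of each focus term are generated by a small
#' number (about 9 to 12) of atom sets, keeping its closure tractable.
#' The Short Focus Level procedure does not need this safeguard -- the
#' root focus level is its recommended default -- so automatic selection
#' is deliberately left unimplemented; this stub documents the interface.
#'
#' @param dag a `gene_set_dag`.
#' @param max_atoms upper bound on atoms per focus term the heuristic
#'   would target.
#' @export
select_focus_level <- function(dag, max_atoms = 12L) {
  stop("automatic focus-level selection is not implemented; ",
       "use validate_focus_level(dag, \"root\") or supply terms explicitly")
}
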