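#' Read an OBO 1.2 ontology file (is_a skeleton)
#'
#' Minimal stanza parser for GO-style OBO files: `[Term]` stanzas are
#' scanned for `id`, `name`, `namespace`, `is_a` and `is_obsolete`.
#' Obsolete terms are skipped; terms are filtered to one namespace
#' (default `biological_process`; stanzas without a namespace line are
#' kept).  Only `is_a` parent/child edges are read; `part_of` and other
#' relationship types are ignored.
#'
#' @param path OBO file path.
#' @param namespace namespace to keep, or `NULL` for all.
#' @return list of class `obo_skeleton`: `terms` (data frame `id`,
#'   `name`, `namespace`) and `edges` (data frame `parent`, `child`,
#'   restricted to edges between kept terms).
#' @export
read_obo <- function(path, namespace = "biological_process") {
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$id) || isTRUE(cur$obsolete)) return(NULL)
    cur
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "[Term]") {
      t <- flush(cur); if (!is.null(t)) terms[[length(terms) + 1L]] <- t
      in_term <- TRUE
      cur <- list(id = NULL, name = NA_character_,
                  namespace = NA_character_, is_a = character(0),
                  obsolete = FALSE)
      next
    }
    if (grepl("^\\[", ln)) {  # some other stanza type
      t <- flush(cur); if (!is.null(t)) terms[[length(terms) + 1L]] <- t
      in_term <- FALSE; cur <- NULL
      next
    }
    if (!in_term || ln == "" || grepl("^!", ln)) next
    if (!grepl("^[A-Za-z_]+:", ln))
      stop("malformed OBO line ", i, ": ", ln)
    key <- sub(":.*$", "", ln)
    val <- trimws(sub("^[A-Za-z_]+:", "", ln))
    val <- trimws(sub("!.*$", "", val))  # strip trailing comments
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$is_a <- c(cur$is_a, val)
    else if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
  }
  t <- flush(cur); if (!is.null(t)) terms[[length(terms) + 1L]] <- t
  if (!length(terms)) stop("no [Term] stanzas found in ", path)

  keep <- if (is.null(namespace)) rep(TRUE, length(terms))
          else vapply(terms, function(t)
            is.na(t$namespace) || t$namespace == namespace, TRUE)
  terms <- terms[keep]
  ids <- vapply(terms, `[[`, "", "id")
  tdf <- data.frame(id = ids,
                    name = vapply(terms, `[[`, "", "name"),
                    namespace = vapply(terms, `[[`, "", "namespace"),
                    stringsAsFactors = FALSE)
  edges <- do.call(rbind, lapply(terms, function(t)
    if (length(t$is_a)) data.frame(parent = t$is_a, child = t$id,
                                   stringsAsFactors = FALSE)))
  if (is.null(edges))
    edges <- data.frame(parent = character(0), child = character(0))
  edges <- edges[edges$parent %in% ids & edges$child %in% ids, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(terms = tdf, edges = edges), class = "obo_skeleton")
}

#' @export
print.obo_skeleton <- function(x, ...) {
  cat("obo_skeleton:", nrow(x$terms), "terms,", nrow(x$edges), "is_a edges\n")
  invisible(x)
}

#' Attach gene annotations to an ontology skeleton
#'
#' Reads a two-column tab-separated file (gene identifier, term
#' identifier; header optional, detected when the second field of the
#' first line is not a known term) and builds a [build_dag()] object.
#' With `propagate = TRUE` (the default, and the assumption the whole
#' testing framework rests on) every annotation is copied to all
#' ancestors of its term, enforcing the true-path rule.  Annotations to
#' unknown terms are skipped with a warning reporting the count.
#'
#' @param path annotation TSV path.
#' @param skeleton an [read_obo()] result, or any list with `terms$id`
#'   and `edges`.
#' @param propagate propagate annotations to ancestors (default `TRUE`).
#' @return a `gene_set_dag` over the annotated terms (terms that end up
#'   with no genes, and are ancestors of none, are dropped).
#' @export
read_annotations <- function(path, skeleton, propagate = TRUE) {
  ann <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(ann) < 2L) stop("annotation file needs two columns: gene, term")
  ann <- ann[, 1:2]
  names(ann) <- c("gene", "term")
  ids <- skeleton$terms$id
  if (!ann$term[1] %in% ids && tolower(ann$term[1]) %in% c("term", "go_id", "term_id"))
    ann <- ann[-1, , drop = FALSE]
  unknown <- !(ann$term %in% ids)
  if (any(unknown)) {
    warning(sum(unknown), " annotation(s) to unknown terms skipped")
    ann <- ann[!unknown, , drop = FALSE]
  }
  if (!nrow(ann)) stop("no usable annotations in ", path)
  membership <- lapply(split(ann$gene, ann$term), unique)
  # restrict the skeleton to terms reachable from annotations
  ed <- normalise_edges(skeleton$edges)
  g <- igraph::graph_from_data_frame(ed, directed = TRUE, vertices = ids)
  keep <- names(membership)
  if (propagate) {
    anc <- lapply(keep, function(v)
      setdiff(names(igraph::subcomponent(g, v, mode = "in")), v))
    keep <- sort(unique(c(keep, unlist(anc, use.names = FALSE))))
  }
  for (t in setdiff(keep, names(membership))) membership[[t]] <- character(0)
  ed <- ed[ed$parent %in% keep & ed$child %in% keep, , drop = FALSE]
  build_dag(ed, membership[keep], propagate = propagate)
}

#' Read a GMT gene-set file
#'
#' Each line: set name, description, then gene identifiers, tab
#' separated.
#'
#' @param path GMT file path.
#' @return named list of gene identifier vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(ln, 1, 60))
    out[[f[1]]] <- unique(f[-(1:2)])
  }
  out
}

#' Read an explicit edge list (parent, child TSV)
#'
#' @param path TSV path with columns parent, child (header optional).
#' @return data frame with columns `parent`, `child`.
#' @export
read_edge_list <- function(path) {
  ed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  ed <- ed[, 1:2]
  names(ed) <- c("parent", "child")
  if (tolower(ed$parent[1]) == "parent") ed <- ed[-1, , drop = FALSE]
  rownames(ed) <- NULL
  ed
}

#' Read a per-identifier p-value TSV
#'
#' Two columns: identifier and p-value; a header row is detected and
#' skipped.
#'
#' @param path TSV path.
#' @return named numeric vector.
#' @export
read_pvalues <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#")
  d <- d[, 1:2]
  if (is.na(suppressWarnings(as.numeric(d[1, 2])))) d <- d[-1, , drop = FALSE]
  p <- as.numeric(d[, 2])
  if (any(is.na(p))) stop("non-numeric p-values in ", path)
  setNames(p, as.character(d[, 1]))
}

#' Write a Short Focus Level result table
#'
#' Tab-separated, UTF-8, one row per tested term with columns `term`,
#' `name` (if known), `stratum`, `raw_p`, `adjusted_p`, `rejected`.
#' Header comment lines record the level, the focus level and the
#' package version so a result file is self-describing.  Rows are sorted
#' by term identifier, so output is deterministic.
#'
#' @param result an [sfl()] result.
#' @param path output TSV path.
#' @param term_names optional named character vector mapping term
#'   identifiers to display names.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, term_names = NULL) {
  stopifnot(inherits(result, "sfl_result"))
  df <- as.data.frame(result)
  df$name <- if (is.null(term_names)) NA_character_
             else unname(term_names[df$term])
  df <- df[order(df$term), c("term", "name", "stratum", "raw_p",
                             "adjusted_p", "rejected")]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("# alpha: ", attr(result, "alpha")),
    paste0("# focus: ", paste(attr(result, "focus"), collapse = ",")),
    paste0("# generator: sfltest ",
           as.character(utils::packageVersion("sfltest")))), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a [write_results()] table
#'
#' @param path TSV path.
#' @return data frame with the written columns.
#' @export
read_results <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Export the significant subgraph as a DOT file
#'
#' Writes only the rejected terms and the DAG edges induced among them.
#' Because Short Focus Level rejections are coherent, every ancestor of a
#' plotted node is plotted too, so the file always depicts an
#' upward-closed subgraph.  Nodes are numbered deterministically (sorted
#' term order) and a label legend is embedded as a comment block.
#'
#' @param result an [sfl()] result.
#' @param dag the `gene_set_dag` the result was computed on.
#' @param path output DOT path.
#' @param term_names optional display names for the legend.
#' @return `path`, invisibly.
#' @export
write_dot <- function(result, dag, path, term_names = NULL) {
  stopifnot(inherits(result, "sfl_result"))
  rej <- sort(intersect(result$term[result$rejected], dag$terms))
  idx <- setNames(seq_along(rej), rej)
  ed <- dag$edges[dag$edges$parent %in% rej & dag$edges$child %in% rej, ,
                  drop = FALSE]
  ed <- ed[order(ed$parent, ed$child), , drop = FALSE]
  lines <- c("digraph significant_subgraph {",
             "  node [shape=circle];")
  for (t in rej) {
    nm <- if (!is.null(term_names) && t %in% names(term_names))
            term_names[[t]] else t
    lines <- c(lines, sprintf("  n%d [label=\"%d\"]; // %s", idx[[t]],
                              idx[[t]], nm))
  }
  if (nrow(ed))
    lines <- c(lines, sprintf("  n%d -> n%d;", idx[ed$parent], idx[ed$child]))
  lines <- c(lines, "}")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
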