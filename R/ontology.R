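#' Build a disease ontology from a child-parent edge list
#'
#' A disease ontology is a rooted directed acyclic graph (DAG) over disease
#' terms, MeSH-style, with edges pointing from a term to its parent(s). For a
#' term `d` the ancestor set `T_d` contains `d` itself plus every term
#' reachable by repeatedly following parent edges; semantic similarity is
#' computed over these shared ancestors.
#'
#' @param edges A data frame whose first two columns are child and parent
#'   identifiers (one directed edge per row). May have zero rows.
#' @param terms Optional character vector of terms; defaults to the union of
#'   edge endpoints. Terms not appearing in any edge are kept as isolated
#'   roots.
#' @return An object of class `disease_ontology` with fields `terms`,
#'   `edges` (tibble with `child`, `parent`), and parent/child adjacency maps.
#' @examples
#' disease_ontology(tibble::tibble(child = c("b", "a"), parent = c("a", "r")))
#' @export
disease_ontology <- function(edges, terms = NULL) {
  edges <- tibble::as_tibble(as.data.frame(edges))
  if (ncol(edges) >= 2L) {
    edges <- edges[, 1:2]
    names(edges) <- c("child", "parent")
    edges$child <- as.character(edges$child)
    edges$parent <- as.character(edges$parent)
  } else if (nrow(edges) == 0L) {
    edges <- tibble::tibble(child = character(), parent = character())
  } else {
    abort("`edges` must have two columns: child, parent.")
  }
  if (any(edges$child == edges$parent)) {
    abort("Self-loop edge detected: a term cannot be its own parent.")
  }
  edges <- dplyr::distinct(edges)
  terms <- sort(unique(c(terms, edges$child, edges$parent)))
  if (length(terms) == 0L) abort("Ontology has no terms.")

  parents <- split(edges$parent, factor(edges$child, levels = terms))
  children <- split(edges$child, factor(edges$parent, levels = terms))

  cyc <- find_cycle(terms, parents)
  if (!is.null(cyc)) {
    abort(sprintf("Ontology contains a cycle: %s", paste(cyc, collapse = " -> ")))
  }

  structure(
    list(terms = terms, edges = edges, parents = parents, children = children),
    class = "disease_ontology"
  )
}

# Kahn's algorithm on the child->parent graph; returns one cycle or NULL.
find_cycle <- function(terms, parents) {
  out <- parents
  remaining <- setNames(vapply(out, length, integer(1)), terms)
  queue <- terms[remaining == 0L]
  child_of <- list()
  for (tm in terms) {
    for (p in out[[tm]]) child_of[[p]] <- c(child_of[[p]], tm)
  }
  seen <- 0L
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in child_of[[v]]) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(terms)) return(NULL)
  # walk parent pointers from an unresolved node until a repeat gives a cycle
  start <- terms[remaining > 0L][1L]
  path <- character()
  v <- start
  while (!(v %in% path)) {
    path <- c(path, v)
    nxt <- Filter(function(p) remaining[[p]] > 0L, out[[v]])
    v <- nxt[[1L]]
  }
  c(path[which(path == v):length(path)], v)
}

#' @export
print.disease_ontology <- function(x, ...) {
  cat(sprintf("<disease_ontology> %d terms, %d edges, %d root(s)\n",
              length(x$terms), nrow(x$edges),
              sum(vapply(x$parents, length, integer(1)) == 0L)))
  invisible(x)
}

#' Read a disease ontology from a two-column TSV edge list
#'
#' Each data row is `child<TAB>parent`. The graph is validated to be acyclic.
#'
#' @param path Path to the edge list. An empty file is allowed only when
#'   `terms` supplies the isolated vocabulary.
#' @param terms Optional term vocabulary (see [disease_ontology()]).
#' @export
read_disease_ontology <- function(path, terms = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_tsv(path, col_names = c("child", "parent"),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) > 0L && tolower(raw$child[1L]) == "child") raw <- raw[-1L, ]
  disease_ontology(raw, terms = terms)
}

#' Write an ontology's edge list as TSV
#' @param x A `disease_ontology`.
#' @param path Output path.
#' @export
write_disease_ontology <- function(x, path) {
  stopifnot(inherits(x, "disease_ontology"))
  readr::write_tsv(x$edges, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Ancestor set of a disease term
#'
#' Returns `T_d`: the term itself plus all ancestors reachable through
#' parent edges.
#'
#' @param ontology A `disease_ontology`.
#' @param d A term identifier.
#' @return Character vector of ancestor identifiers (including `d`).
#' @export
ancestor_set <- function(ontology, d) {
  stopifnot(inherits(ontology, "disease_ontology"))
  if (!d %in% ontology$terms) abort(sprintf("Unknown disease term: %s", d))
  seen <- character()
  frontier <- d
  while (length(frontier) > 0L) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(ontology$parents[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  sort(unique(seen))
}
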