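#' Build a circRNA-disease association matrix from a pair table
#'
#' The association matrix `A` is an `n x m` binary matrix over `n` circRNAs
#' (rows) and `m` diseases (columns), with `A[i, j] = 1` for every
#' experimentally supported circRNA-disease pair and 0 elsewhere. Duplicate
#' pairs in the input are collapsed to a single 1, and identifiers are sorted
#' lexicographically so that all downstream matrices have a deterministic row
#' and column order.
#'
#' @param pairs A data frame whose first two columns are circRNA and disease
#'   identifiers (one row per reported association).
#' @return An object of class `association_matrix`: a list with `values`
#'   (binary matrix with dimnames), `circ_ids`, and `disease_ids`.
#' @examples
#' pairs <- tibble::tibble(circrna = c("c1", "c2", "c1"), disease = c("d1", "d1", "d1"))
#' as_association_matrix(pairs)
#' @export
as_association_matrix <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2L) abort("`pairs` must have at least two columns (circRNA, disease).")
  circ <- as.character(pairs[[1L]])
  dis <- as.character(pairs[[2L]])
  bad <- which(is.na(circ) | is.na(dis) | circ == "" | dis == "")
  if (length(bad) > 0L) {
    abort(sprintf("Malformed association row(s): %s (empty or missing identifier).",
                  paste(head(bad, 5L), collapse = ", ")))
  }
  if (length(circ) == 0L) abort("No association rows supplied.")
  circ_ids <- sort(unique(circ))
  disease_ids <- sort(unique(dis))
  values <- matrix(0, nrow = length(circ_ids), ncol = length(disease_ids),
                   dimnames = list(circ_ids, disease_ids))
  values[cbind(match(circ, circ_ids), match(dis, disease_ids))] <- 1
  new_association_matrix(values, circ_ids, disease_ids)
}

#' Low-level association matrix constructor
#'
#' Validates and wraps an existing binary matrix; use
#' [as_association_matrix()] for pair tables.
#'
#' @param values Binary `n x m` matrix.
#' @param circ_ids,disease_ids Row / column identifiers.
#' @export
new_association_matrix <- function(values, circ_ids, disease_ids) {
  stopifnot(nrow(values) == length(circ_ids), ncol(values) == length(disease_ids))
  if (anyDuplicated(circ_ids) || anyDuplicated(disease_ids)) {
    abort("Duplicate identifiers in association matrix.")
  }
  if (!all(values %in% c(0, 1))) abort("Association matrix entries must be 0 or 1.")
  dimnames(values) <- list(circ_ids, disease_ids)
  structure(
    list(values = values, circ_ids = circ_ids, disease_ids = disease_ids),
    class = "association_matrix"
  )
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("<association_matrix> %d circRNAs x %d diseases, %d known associations (density %.3f)\n",
              nrow(x$values), ncol(x$values), sum(x$values),
              mean(x$values)))
  invisible(x)
}

#' @export
dim.association_matrix <- function(x) dim(x$values)

#' Read a circRNA-disease association list from a delimited file
#'
#' Expects a two-column text table (circRNA identifier, disease identifier),
#' with an optional header line. An optional exclusion-list file can remove
#' curated pairs (e.g. non-human records) before the matrix is built.
#'
#' @param path Path to the association table.
#' @param dialect `"tsv"` or `"csv"`.
#' @param exclude Optional path to a two-column table of pairs to drop.
#' @return An [as_association_matrix()] result.
#' @export
read_association_list <- function(path, dialect = c("tsv", "csv"), exclude = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- tryCatch(
    reader(path, col_names = FALSE,
           col_types = readr::cols(.default = readr::col_character()),
           progress = FALSE, show_col_types = FALSE),
    error = function(e) abort(sprintf("Failed to parse %s: %s", path, conditionMessage(e)))
  )
  if (ncol(raw) < 2L || nrow(raw) == 0L) abort(sprintf("Empty or malformed association file: %s", path))
  pairs <- raw[, 1:2]
  names(pairs) <- c("circrna", "disease")
  # optional header line
  if (tolower(pairs$circrna[1L]) %in% c("circrna", "circ", "circ_id") ||
      tolower(pairs$disease[1L]) %in% c("disease", "disease_id")) {
    pairs <- pairs[-1L, ]
    if (nrow(pairs) == 0L) abort(sprintf("Empty association file: %s", path))
  }
  bad <- which(is.na(pairs$circrna) | is.na(pairs$disease))
  if (length(bad) > 0L) {
    abort(sprintf("Malformed row at line %d of %s.", bad[1L], path))
  }
  if (!is.null(exclude)) {
    excl <- readr::read_tsv(exclude, col_types = readr::cols(.default = readr::col_character()),
                            col_names = c("circrna", "disease"), progress = FALSE, show_col_types = FALSE)
    pairs <- dplyr::anti_join(pairs, excl, by = c("circrna", "disease"))
    if (nrow(pairs) == 0L) abort("All associations removed by the exclusion list.")
  }
  as_association_matrix(pairs)
}

#' Convert an association matrix back to a tidy pair table
#'
#' @param x An `association_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `circrna` and `disease`, one row per known
#'   association, in lexicographic order.
#' @export
tidy.association_matrix <- function(x, ...) {
  idx <- which(x$values == 1, arr.ind = TRUE)
  out <- tibble::tibble(
    circrna = x$circ_ids[idx[, 1L]],
    disease = x$disease_ids[idx[, 2L]]
  )
  dplyr::arrange(out, .data$circrna, .data$disease)
}

#' Write an association matrix as a two-column TSV pair list
#'
#' @param x An `association_matrix`.
#' @param path Output path.
#' @export
write_association_list <- function(x, path) {
  stopifnot(inherits(x, "association_matrix"))
  readr::write_tsv(tidy(x), path, progress = FALSE)
  invisible(path)
}

#' Write ranked association scores to a TSV file
#'
#' Rows are sorted by descending score; ties are broken by circRNA then
#' disease identifier so output is reproducible byte-for-byte.
#'
#' @param scores A data frame with columns `circrna`, `disease`, `score`
#'   (scores in `[0, 1]`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_scores <- function(scores, path) {
  scores <- tibble::as_tibble(scores)
  req <- c("circrna", "disease", "score")
  if (!all(req %in% names(scores))) {
    abort("`scores` needs columns circrna, disease, score.")
  }
  if (nrow(scores) > 0 && (any(scores$score < 0) || any(scores$score > 1))) {
    abort("Scores must lie in [0, 1].")
  }
  out <- dplyr::arrange(scores[, req], dplyr::desc(.data$score), .data$circrna, .data$disease)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
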