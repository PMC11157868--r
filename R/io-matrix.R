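#' Write a similarity (or embedding) matrix to disk
#'
#' Dense matrices go to TSV with a leading identifier column and identifier
#' header row. Paths ending in `.mtx` are written as sparse MatrixMarket
#' files, with row/column identifiers in `<path>.rows` / `<path>.cols`
#' sidecar files.
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output path (`.tsv` or `.mtx`).
#' @export
write_similarity_matrix <- function(x, path) {
  x <- as.matrix(unclass(x))
  if (grepl("\\.mtx$", path)) {
    if (!requireNamespace("Matrix", quietly = TRUE)) abort("Package 'Matrix' required for MTX output.")
    Matrix::writeMM(Matrix::Matrix(x, sparse = TRUE), path)
    writeLines(rownames(x) %||% as.character(seq_len(nrow(x))), paste0(path, ".rows"))
    writeLines(colnames(x) %||% as.character(seq_len(ncol(x))), paste0(path, ".cols"))
  } else {
    df <- tibble::as_tibble(as.data.frame(x), rownames = "id")
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a similarity (or embedding) matrix written by [write_similarity_matrix()]
#'
#' @param path `.tsv` (dense, id header) or `.mtx` (sparse MatrixMarket with
#'   `.rows`/`.cols` sidecars).
#' @return A numeric matrix with dimnames.
#' @export
read_similarity_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (grepl("\\.mtx$", path)) {
    if (!requireNamespace("Matrix", quietly = TRUE)) abort("Package 'Matrix' required for MTX input.")
    m <- as.matrix(Matrix::readMM(path))
    storage.mode(m) <- "double"  # a binary matrix round-trips via MM "pattern"
    rows <- paste0(path, ".rows"); cols <- paste0(path, ".cols")
    if (file.exists(rows)) rownames(m) <- readLines(rows)
    if (file.exists(cols)) colnames(m) <- readLines(cols)
    return(m)
  }
  df <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE, show_col_types = FALSE)
  m <- as.matrix(df[, -1L])
  rownames(m) <- df$id
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
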