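#' Semantic contribution of ancestors to a disease term
#'
#' Within the ontology DAG, each ancestor `d` of a target term `d_i`
#' contributes semantically to `d_i` with a value that decays with distance:
#' the target contributes 1, and any other ancestor contributes
#' `max(gamma * SC(d'))` over its children `d'` that are themselves ancestors
#' of `d_i` (or `d_i` itself). With `gamma <= 1` this equals `gamma`
#' raised to the shortest downward path length to the target.
#'
#' @param ontology A `disease_ontology`.
#' @param d_i Target disease term.
#' @param gamma Semantic contribution (decay) factor in `(0, 1]`; default 0.5.
#' @return Object of class `semantic_contribution`: a list with `target`,
#'   `gamma`, and `contributions` (named numeric over the ancestor set).
#' @export
semantic_contribution <- function(ontology, d_i, gamma = 0.5) {
  stopifnot(inherits(ontology, "disease_ontology"))
  if (!is.numeric(gamma) || gamma <= 0 || gamma > 1) abort("`gamma` must be in (0, 1].")
  t_d <- ancestor_set(ontology, d_i)
  memo <- new.env(parent = emptyenv())
  assign(d_i, 1, envir = memo)
  sc <- function(a) {
    if (exists(a, envir = memo, inherits = FALSE)) return(get(a, envir = memo))
    kids <- intersect(ontology$children[[a]], t_d)
    val <- max(gamma * vapply(kids, sc, numeric(1)))
    assign(a, val, envir = memo)
    val
  }
  contributions <- vapply(t_d, sc, numeric(1))
  structure(
    list(target = d_i, gamma = gamma, contributions = contributions),
    class = "semantic_contribution"
  )
}

#' Semantic value of a disease term
#'
#' The sum of the semantic contributions of all ancestors of the target,
#' always at least 1 (the target's own contribution).
#'
#' @param sc A [semantic_contribution()] result.
#' @return A scalar `>= 1`.
#' @export
semantic_value <- function(sc) {
  stopifnot(inherits(sc, "semantic_contribution"))
  sum(sc$contributions)
}

#' Disease semantic similarity matrix (DS)
#'
#' Similarity between two disease terms is the summed contribution of their
#' shared ancestors, normalised by the two semantic values:
#' `DS(d_i, d_j) = sum over shared ancestors of (SC_i + SC_j) / (SV_i + SV_j)`.
#' Diagonal entries are exactly 1; terms with disjoint ancestor sets score 0.
#'
#' Diseases absent from the ontology are handled with `T_d = {d}`
#' (self-similarity 1, zero cross-similarity) and a warning; the downstream
#' Gaussian-kernel fallback fills those rows during similarity integration.
#'
#' @param ontology A `disease_ontology`.
#' @param diseases Ordered disease identifiers for rows/columns.
#' @param gamma Decay factor passed to [semantic_contribution()].
#' @return A symmetric `m x m` matrix with unit diagonal, entries in `[0, 1]`.
#' @export
disease_semantic_similarity <- function(ontology, diseases, gamma = 0.5) {
  stopifnot(inherits(ontology, "disease_ontology"))
  missing_terms <- setdiff(diseases, ontology$terms)
  if (length(missing_terms) > 0L) {
    warn(sprintf("%d disease(s) absent from the ontology; using T_d = {d}: %s",
                 length(missing_terms),
                 paste(head(missing_terms, 5L), collapse = ", ")))
  }
  scs <- lapply(diseases, function(d) {
    if (d %in% ontology$terms) {
      semantic_contribution(ontology, d, gamma)$contributions
    } else {
      setNames(1, d)
    }
  })
  svs <- vapply(scs, sum, numeric(1))
  m <- length(diseases)
  ds <- matrix(0, m, m, dimnames = list(diseases, diseases))
  for (i in seq_len(m)) {
    for (j in i:m) {
      shared <- intersect(names(scs[[i]]), names(scs[[j]]))
      num <- if (length(shared) > 0L) sum(scs[[i]][shared]) + sum(scs[[j]][shared]) else 0
      ds[i, j] <- ds[j, i] <- num / (svs[i] + svs[j])
    }
  }
  diag(ds) <- 1
  similarity_matrix(ds, kind = "DS")
}

similarity_matrix <- function(values, kind) {
  structure(values, kind = kind, class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix kind=%s> %d x %d\n", attr(x, "kind"), nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x))), drop = FALSE])
  invisible(x)
}

#' circRNA functional similarity matrix (FS)
#'
#' Two circRNAs are functionally similar when their associated disease sets
#' are semantically similar: with `T_i` the diseases of `c_i` (size `r`) and
#' `T_j` those of `c_j` (size `l`),
#' `FS = (sum_{d in T_i} bestmatch(d, T_j) + sum_{d in T_j} bestmatch(d, T_i)) / (r + l)`
#' where `bestmatch(d, T)` is the maximum semantic similarity of `d` to any
#' member of `T`. If either disease set is empty, FS is 0.
#'
#' @param A An `association_matrix`.
#' @param DS Disease semantic similarity matrix covering the diseases of `A`.
#' @return A symmetric `n x n` matrix; diagonal is 1 for circRNAs with at
#'   least one association.
#' @export
circrna_functional_similarity <- function(A, DS) {
  stopifnot(inherits(A, "association_matrix"))
  if (!all(A$disease_ids %in% rownames(DS))) {
    abort("`DS` does not cover all diseases of the association matrix.")
  }
  ds <- unclass(DS)[A$disease_ids, A$disease_ids, drop = FALSE]
  n <- length(A$circ_ids)
  sets <- apply(A$values, 1L, function(row) which(row == 1), simplify = FALSE)
  fs <- matrix(0, n, n, dimnames = list(A$circ_ids, A$circ_ids))
  for (i in seq_len(n)) {
    ti <- sets[[i]]
    if (length(ti) == 0L) next
    for (j in i:n) {
      tj <- sets[[j]]
      if (length(tj) == 0L) next
      sub <- ds[ti, tj, drop = FALSE]
      val <- (sum(apply(sub, 1L, max)) + sum(apply(sub, 2L, max))) /
        (length(ti) + length(tj))
      fs[i, j] <- fs[j, i] <- val
    }
  }
  similarity_matrix(fs, kind = "FS")
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' The interaction profile of a circRNA is its row of the association matrix
#' (for diseases, its column). Similarity is a Gaussian kernel on profile
#' distance, `exp(-lambda * ||profile_i - profile_j||^2)`, with bandwidth
#' `lambda = p / sum_i ||profile_i||^2` where `p` is the number of profiles —
#' i.e. the kernel width adapts to the average profile norm.
#'
#' @param A An `association_matrix` with at least one known association.
#' @param axis `"circrna"` (rows; kernel CK) or `"disease"` (columns; DK).
#' @return A symmetric matrix with diagonal exactly 1 and entries in `(0, 1]`.
#' @export
gip_kernel <- function(A, axis = c("circrna", "disease")) {
  stopifnot(inherits(A, "association_matrix"))
  axis <- match.arg(axis)
  profiles <- if (axis == "circrna") A$values else t(A$values)
  total <- sum(profiles^2)
  if (total == 0) abort("GIP kernel undefined: association matrix is all-zero.")
  lambda <- nrow(profiles) / total
  d2 <- as.matrix(dist(profiles))^2
  k <- exp(-lambda * d2)
  diag(k) <- 1
  ids <- rownames(profiles)
  dimnames(k) <- list(ids, ids)
  similarity_matrix(k, kind = if (axis == "circrna") "CK" else "DK")
}

#' Integrate a primary similarity with a kernel fallback
#'
#' Elementwise: keep the primary similarity where it is nonzero, otherwise
#' fall back to the secondary one. Used to patch the sparse functional /
#' semantic similarities with the dense Gaussian kernels (FS patched by CK
#' for circRNAs; DS patched by DK for diseases).
#'
#' @param primary,fallback Square matrices of identical shape and id order.
#' @return A `similarity_matrix` of the same shape.
#' @export
integrate_similarity <- function(primary, fallback) {
  if (!all(dim(primary) == dim(fallback))) abort("Shape mismatch between similarity matrices.")
  if (!is.null(rownames(primary)) && !is.null(rownames(fallback)) &&
      !identical(rownames(primary), rownames(fallback))) {
    abort("Identifier order differs between similarity matrices.")
  }
  p <- unclass(primary); f <- unclass(fallback)
  out <- ifelse(p != 0, p, f)
  dimnames(out) <- dimnames(p)
  kind <- if (identical(attr(primary, "kind"), "FS")) "Xc" else
    if (identical(attr(primary, "kind"), "DS")) "Xd" else "integrated"
  similarity_matrix(out, kind = kind)
}

#' Heterogeneous circRNA-disease network adjacency (CDHN)
#'
#' Builds the block adjacency `X = [[0, A], [A^T, 0]]` of the bipartite
#' circRNA-disease graph: an `(n+m) x (n+m)` symmetric matrix whose node
#' order is circRNAs followed by diseases, with zero diagonal blocks.
#'
#' @param A An `association_matrix`.
#' @return Object of class `heterogeneous_adjacency` (a matrix with a
#'   `node_ids` attribute).
#' @export
build_heterogeneous_adjacency <- function(A) {
  stopifnot(inherits(A, "association_matrix"))
  n <- length(A$circ_ids); m <- length(A$disease_ids)
  x <- rbind(
    cbind(matrix(0, n, n), A$values),
    cbind(t(A$values), matrix(0, m, m))
  )
  node_ids <- c(A$circ_ids, A$disease_ids)
  dimnames(x) <- list(node_ids, node_ids)
  structure(x, node_ids = node_ids, n_circ = n, n_disease = m,
            class = c("heterogeneous_adjacency", "matrix", "array"))
}

#' @export
print.heterogeneous_adjacency <- function(x, ...) {
  cat(sprintf("<heterogeneous_adjacency> %d nodes (%d circRNAs + %d diseases), %d edges\n",
              nrow(x), attr(x, "n_circ"), attr(x, "n_disease"), sum(unclass(x) != 0) / 2))
  invisible(x)
}
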