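#' Generate a synthetic circRNA-disease benchmark with planted structure
#'
#' Emulates the statistical shape of a curated circRNA-disease association
#' resource: a sparse binary bipartite matrix whose positives follow a planted
#' low-rank structure (so that similarity-based link prediction has signal to
#' recover), plus a random rooted DAG over the disease terms for semantic
#' similarity. Association scores are drawn as the product of two
#' non-negative rank-`latent_rank` factor matrices and the `n_pos` highest
#' cells are marked as known associations.
#'
#' The DAG is a random recursive tree constrained to depth `dag_depth`, with
#' a small fraction of extra child-to-ancestor edges so some terms have
#' multiple parents (exercising the max-over-parents semantic recursion).
#'
#' @param n Number of circRNAs.
#' @param m Number of diseases.
#' @param n_pos Number of known associations to plant (`n_pos <= n * m`).
#' @param latent_rank Rank of the planted score structure.
#' @param dag_depth Maximum depth of the disease DAG (root has depth 1).
#' @param seed Integer seed; the output is bit-reproducible given the seed.
#' @param extra_edge_frac Fraction of non-root terms that receive one extra
#'   parent edge to a deeper ancestor (default 0.15).
#' @return A list with `associations` (an `association_matrix`) and
#'   `ontology` (a `disease_ontology` over the same disease identifiers).
#' @examples
#' fx <- generate_synthetic_dataset(n = 10, m = 5, n_pos = 8, latent_rank = 2,
#'                                  dag_depth = 3, seed = 1)
#' sum(fx$associations$values)  # 8
#' @export
generate_synthetic_dataset <- function(n = 100, m = 30, n_pos = 300,
                                       latent_rank = 3, dag_depth = 4,
                                       seed = 1, extra_edge_frac = 0.15) {
  n <- check_scalar_int(n, "n"); m <- check_scalar_int(m, "m")
  n_pos <- check_scalar_int(n_pos, "n_pos")
  latent_rank <- check_scalar_int(latent_rank, "latent_rank")
  dag_depth <- check_scalar_int(dag_depth, "dag_depth")
  if (n_pos > n * m) abort("`n_pos` cannot exceed n * m.")

  circ_ids <- sprintf("circ%03d", seq_len(n))
  disease_ids <- sprintf("dis%03d", seq_len(m))

  values <- with_local_seed(derive_seed(seed, "assoc"), {
    u <- matrix(rgamma_safe(n * latent_rank), n, latent_rank)
    v <- matrix(rgamma_safe(m * latent_rank), m, latent_rank)
    s <- u %*% t(v)
    a <- matrix(0, n, m)
    top <- order(-as.vector(s), seq_along(s))[seq_len(n_pos)]
    a[top] <- 1
    a
  })
  # identifiers are assigned in lexicographic order already
  assoc <- new_association_matrix(values, circ_ids, disease_ids)

  ontology <- with_local_seed(derive_seed(seed, "dag"), {
    random_rooted_dag(disease_ids, dag_depth, extra_edge_frac)
  })

  list(associations = assoc, ontology = ontology)
}

# gamma(2, 1) draws: non-negative, right-skewed factor loadings
rgamma_safe <- function(k) stats::rgamma(k, shape = 2, rate = 1)

random_rooted_dag <- function(ids, max_depth, extra_edge_frac) {
  m <- length(ids)
  depth <- c(1L, rep(NA_integer_, m - 1L))
  child <- character(); parent <- character()
  for (i in seq_len(m)[-1]) {
    candidates <- which(!is.na(depth) & depth < max_depth)
    p <- if (length(candidates) == 1L) candidates else sample(candidates, 1L)
    depth[i] <- depth[p] + 1L
    child <- c(child, ids[i]); parent <- c(parent, ids[p])
  }
  # extra child -> strict-ancestor edges create multi-parent (diamond) terms
  if (m > 2L) {
    parent_of <- setNames(parent, child)
    eligible <- which(depth >= 3L)
    n_extra <- floor(extra_edge_frac * (m - 1L))
    if (length(eligible) > 0L && n_extra > 0L) {
      picks <- sample(eligible, min(n_extra, length(eligible)))
      for (i in picks) {
        anc <- character(); v <- ids[i]
        repeat {
          p <- unname(parent_of[v])
          if (is.na(p)) break
          anc <- c(anc, p)
          v <- p
        }
        anc <- setdiff(anc, parent_of[[ids[i]]])  # skip the existing parent
        if (length(anc) > 0L) {
          a <- if (length(anc) == 1L) anc else sample(anc, 1L)
          child <- c(child, ids[i]); parent <- c(parent, a)
        }
      }
    }
  }
  disease_ontology(tibble::tibble(child = child, parent = parent), terms = ids)
}
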