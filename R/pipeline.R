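#' Pipeline configuration
#'
#' Collects the tunable parameters of the association-prediction pipeline.
#' Defaults follow the method's reference configuration: embedding width
#' `k = 64`, semantic decay `gamma = 0.5`, a two-layer graph-convolutional
#' propagation, and biased walks with return parameter `p = 1` and in-out
#' parameter `q = 0.25` (depth-first leaning). `k` must not exceed the
#' smaller side of the association matrix (the auto-encoder cannot widen its
#' input), so small benchmarks need a smaller `k`.
#'
#' @param k Embedding width for the auto-encoder, GCN, and walk embedding.
#' @param gamma Semantic contribution decay factor in `(0, 1]`.
#' @param ae_epochs,ae_lr,ae_l1 Auto-encoder training epochs, learning rate,
#'   and L1 activation penalty.
#' @param ae_objective `"hidden_output"` (default) or `"reconstruction"`;
#'   see [train_autoencoder()].
#' @param gcn_depth Number of propagation layers (default 2).
#' @param walk A [walk_config()].
#' @param neg_ratio Training negatives per positive (default 1).
#' @param pair_mode Pair feature construction: `"concat"` or `"hadamard"`.
#' @param threshold Classification threshold for the thresholded metrics.
#' @param num_trees Trees for the ensemble classifiers.
#' @export
cda_config <- function(k = 64, gamma = 0.5, ae_epochs = 200, ae_lr = 1e-3,
                       ae_l1 = 0, ae_objective = "hidden_output",
                       gcn_depth = 2, walk = walk_config(), neg_ratio = 1,
                       pair_mode = "concat", threshold = 0.5, num_trees = 100) {
  structure(
    list(k = check_scalar_int(k, "k"), gamma = gamma, ae_epochs = ae_epochs,
         ae_lr = ae_lr, ae_l1 = ae_l1, ae_objective = ae_objective,
         gcn_depth = gcn_depth, walk = walk, neg_ratio = neg_ratio,
         pair_mode = pair_mode, threshold = threshold, num_trees = num_trees),
    class = "cda_config"
  )
}

#' Build all similarity and embedding artifacts from an association matrix
#'
#' Runs the representation half of the pipeline: disease semantic similarity
#' (DS) and circRNA functional similarity (FS) from the ontology and the
#' association matrix; Gaussian interaction profile kernels (CK, DK);
#' integrated similarities (`Xc = FS patched by CK`, `Xd = DS patched by
#' DK`); sparse auto-encoder features `Q`; the CDHN block adjacency; the
#' local GCN embedding `Hl`; the global walk embedding `Hg`; and the fused
#' embedding `H = Hl || Hg`.
#'
#' Every artifact depends only on the association matrix passed in, so
#' calling this on a training fold (held-out positives zeroed) guarantees
#' the held-out pairs cannot leak into any representation.
#'
#' @param assoc An `association_matrix` (e.g. the training fold).
#' @param ontology A `disease_ontology`.
#' @param config A [cda_config()].
#' @param seed Integer seed driving the auto-encoder initialisations, GCN
#'   weights, walk simulation, and skip-gram training.
#' @return A list with elements `DS`, `FS`, `CK`, `DK`, `Xc`, `Xd`, `Q`,
#'   `X` (CDHN), `Hl`, `Hg`, `H`, and `n_circ`.
#' @export
build_embedding <- function(assoc, ontology, config = cda_config(), seed = 1) {
  stopifnot(inherits(assoc, "association_matrix"))
  n <- length(assoc$circ_ids); m <- length(assoc$disease_ids)
  if (config$k > min(n, m)) {
    abort(sprintf(
      "Embedding width k = %d exceeds min(n, m) = %d; pass cda_config(k = ...) with a smaller width.",
      config$k, min(n, m)))
  }
  ds <- disease_semantic_similarity(ontology, assoc$disease_ids, gamma = config$gamma)
  fs <- circrna_functional_similarity(assoc, ds)
  ck <- gip_kernel(assoc, "circrna")
  dk <- gip_kernel(assoc, "disease")
  xc <- integrate_similarity(fs, ck)
  xd <- integrate_similarity(ds, dk)

  ae_c <- train_autoencoder(xc, k = config$k, epochs = config$ae_epochs,
                            lr = config$ae_lr, l1_penalty = config$ae_l1,
                            seed = derive_seed(seed, "ae-circ"),
                            objective = config$ae_objective)
  ae_d <- train_autoencoder(xd, k = config$k, epochs = config$ae_epochs,
                            lr = config$ae_lr, l1_penalty = config$ae_l1,
                            seed = derive_seed(seed, "ae-disease"),
                            objective = config$ae_objective)
  q <- build_node_features(ae_c$Z, ae_d$Z)

  x <- build_heterogeneous_adjacency(assoc)
  hl <- gcn_embed(x, q, depth = config$gcn_depth, seed = derive_seed(seed, "gcn"))
  hg <- node2vec_embed(x, k = config$k, cfg = config$walk,
                       seed = derive_seed(seed, "node2vec"))
  h <- fuse_embeddings(hl, hg)

  list(DS = ds, FS = fs, CK = ck, DK = dk, Xc = xc, Xd = xd, Q = q, X = x,
       Hl = hl, Hg = hg, H = h, n_circ = n)
}

#' Fit the full association-prediction model
#'
#' Builds all similarity and embedding artifacts from the supplied
#' association matrix, assembles a balanced training set (all known
#' associations plus `neg_ratio` uniformly sampled unknown pairs), and
#' trains the classifier on the fused pair features.
#'
#' @inheritParams build_embedding
#' @param classifier Classifier kind (default `"et"`, extra trees).
#' @param scheme Embedding scheme fed to the classifier: `"both"`,
#'   `"local_only"`, or `"global_only"`.
#' @return A `cda_model` object; use [predict.cda_model()] or
#'   [rank_for_disease()] to score candidates.
#' @export
cda_fit <- function(assoc, ontology, config = cda_config(), classifier = "et",
                    scheme = c("both", "local_only", "global_only"), seed = 1) {
  scheme <- match.arg(scheme)
  emb <- build_embedding(assoc, ontology, config, seed = derive_seed(seed, "fit-emb"))
  pos <- which(assoc$values == 1, arr.ind = TRUE)
  dimnames(pos) <- list(NULL, c("circ_index", "disease_index"))
  neg <- sample_negatives(assoc, ratio = config$neg_ratio,
                          seed = derive_seed(seed, "fit-neg"))
  h_use <- switch(scheme, local_only = emb$Hl, global_only = emb$Hg, both = emb$H)
  pairs <- rbind(pos, neg)
  labels <- rep(c(1L, 0L), c(nrow(pos), nrow(neg)))
  feats <- make_pair_features(h_use, pairs, emb$n_circ, mode = config$pair_mode)
  model <- train_classifier(feats, labels, kind = classifier,
                            seed = derive_seed(seed, "fit-clf"),
                            num_trees = config$num_trees)
  structure(
    list(assoc = assoc, embedding = emb, model = model, scheme = scheme,
         classifier = classifier, config = config, seed = seed),
    class = "cda_model"
  )
}

#' @export
print.cda_model <- function(x, ...) {
  cat(sprintf("<cda_model> %d circRNAs x %d diseases, scheme '%s', classifier '%s'\n",
              length(x$assoc$circ_ids), length(x$assoc$disease_ids),
              x$scheme, x$classifier))
  invisible(x)
}

#' Score circRNA-disease pairs with a fitted model
#'
#' @param object A `cda_model`.
#' @param pairs Data frame with columns `circrna` and `disease`
#'   (identifiers). Defaults to all `n x m` pairs.
#' @param ... Unused.
#' @return Tibble with `circrna`, `disease`, `score`.
#' @export
predict.cda_model <- function(object, pairs = NULL, ...) {
  assoc <- object$assoc
  if (is.null(pairs)) {
    pairs <- tidyr::expand_grid(circrna = assoc$circ_ids, disease = assoc$disease_ids)
  }
  pairs <- tibble::as_tibble(pairs)
  ci <- match(pairs$circrna, assoc$circ_ids)
  dj <- match(pairs$disease, assoc$disease_ids)
  if (anyNA(ci)) abort(sprintf("Unknown circRNA: %s", pairs$circrna[which(is.na(ci))[1L]]))
  if (anyNA(dj)) abort(sprintf("Unknown disease: %s", pairs$disease[which(is.na(dj))[1L]]))
  h_use <- switch(object$scheme, local_only = object$embedding$Hl,
                  global_only = object$embedding$Hg, both = object$embedding$H)
  feats <- make_pair_features(h_use, cbind(ci, dj), object$embedding$n_circ,
                              mode = object$config$pair_mode)
  tibble::tibble(circrna = pairs$circrna, disease = pairs$disease,
                 score = score_pairs(object$model, feats))
}

#' Rank novel circRNA candidates for a disease
#'
#' Scores every circRNA without a known association to the given disease and
#' returns the top candidates by score (ties broken lexicographically by
#' circRNA identifier).
#'
#' @param object A `cda_model`.
#' @param disease A disease identifier present in the model.
#' @param top_k Number of candidates to return (default 10).
#' @return Tibble with `rank`, `circrna`, `disease`, `score`.
#' @export
rank_for_disease <- function(object, disease, top_k = 10) {
  stopifnot(inherits(object, "cda_model"))
  assoc <- object$assoc
  dj <- match(disease, assoc$disease_ids)
  if (is.na(dj)) abort(sprintf("Unknown disease: %s", disease))
  candidates <- assoc$circ_ids[assoc$values[, dj] == 0]
  if (length(candidates) == 0L) return(tibble::tibble(
    rank = integer(), circrna = character(), disease = character(), score = numeric()))
  scored <- predict(object, tibble::tibble(circrna = candidates, disease = disease))
  scored |>
    dplyr::arrange(dplyr::desc(.data$score), .data$circrna) |>
    dplyr::slice_head(n = top_k) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1L)
}

#' Model-level summary of a fitted association model
#' @param x A `cda_model`.
#' @param ... Unused.
#' @return One-row tibble with dataset and configuration facts.
#' @export
glance.cda_model <- function(x, ...) {
  tibble::tibble(
    n_circrna = length(x$assoc$circ_ids),
    n_disease = length(x$assoc$disease_ids),
    n_positive = sum(x$assoc$values),
    embed_width = x$config$k,
    scheme = x$scheme,
    classifier = x$classifier,
    seed = x$seed
  )
}

#' Per-node embedding table of a fitted model
#' @param x A `cda_model`.
#' @param ... Unused.
#' @return Tibble with `node`, `type`, and one column per fused embedding
#'   dimension.
#' @export
tidy.cda_model <- function(x, ...) {
  h <- x$embedding$H
  n <- x$embedding$n_circ
  out <- tibble::as_tibble(as.data.frame(h), .name_repair = ~ paste0("h", seq_along(.x)))
  dplyr::bind_cols(
    tibble::tibble(
      node = c(x$assoc$circ_ids, x$assoc$disease_ids),
      type = rep(c("circrna", "disease"), c(n, nrow(h) - n))
    ),
    out
  )
}
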