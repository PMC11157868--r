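#' Fuse the local and global embeddings
#'
#' Concatenates the GCN-derived local embedding and the walk-derived global
#' embedding column-wise (`H = H_l || H_g`, local block first), preserving
#' node order.
#'
#' @param Hl,Hg `(n+m) x k` embedding matrices over the same nodes.
#' @return `(n+m) x 2k` fused embedding with attribute `source = "fused"`.
#' @export
fuse_embeddings <- function(Hl, Hg) {
  Hl <- as.matrix(Hl); Hg <- as.matrix(Hg)
  if (nrow(Hl) != nrow(Hg)) {
    abort(sprintf("Row mismatch: local %d vs global %d.", nrow(Hl), nrow(Hg)))
  }
  h <- cbind(Hl, Hg)
  rownames(h) <- rownames(Hl)
  attr(h, "source") <- "fused"
  h
}

#' Build per-pair feature vectors from a node embedding
#'
#' A candidate pair `(c_i, d_j)` is represented by the concatenation of the
#' circRNA's embedding row and the disease's embedding row (row `n + j` of
#' `H`), giving vectors of twice the embedding width. An elementwise-product
#' variant (`mode = "hadamard"`, width `k`) is available.
#'
#' @param H `(n+m) x k` embedding matrix (circRNA rows first).
#' @param pairs Two-column matrix or data frame of (circRNA index, disease
#'   index), both 1-based.
#' @param n_circ Number of circRNA rows in `H`.
#' @param mode `"concat"` (default) or `"hadamard"`.
#' @return Numeric feature matrix with one row per pair.
#' @export
make_pair_features <- function(H, pairs, n_circ, mode = c("concat", "hadamard")) {
  mode <- match.arg(mode)
  H <- as.matrix(H)
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  storage.mode(pairs) <- "integer"
  m <- nrow(H) - n_circ
  if (any(pairs[, 1L] < 1L | pairs[, 1L] > n_circ)) abort("circRNA index out of range.")
  if (any(pairs[, 2L] < 1L | pairs[, 2L] > m)) abort("Disease index out of range.")
  ci <- H[pairs[, 1L], , drop = FALSE]
  dj <- H[n_circ + pairs[, 2L], , drop = FALSE]
  feats <- if (mode == "concat") cbind(ci, dj) else ci * dj
  rownames(feats) <- NULL
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  feats
}

#' Sample negative (unknown) circRNA-disease pairs
#'
#' Draws `ceiling(ratio * n_positives)` cells with `A = 0` uniformly without
#' replacement, optionally excluding a given pair set (e.g. held-out test
#' pairs).
#'
#' @param A An `association_matrix`.
#' @param ratio Negatives per positive (default 1, i.e. a balanced design).
#' @param seed Integer seed.
#' @param exclude Optional two-column matrix of (circRNA index, disease
#'   index) pairs that must not be sampled.
#' @param n Optional explicit number of negatives, overriding `ratio`.
#' @return Integer matrix with columns `circ_index`, `disease_index`.
#' @export
sample_negatives <- function(A, ratio = 1, seed = 1, exclude = NULL, n = NULL) {
  stopifnot(inherits(A, "association_matrix"))
  n_pos <- sum(A$values)
  need <- if (is.null(n)) ceiling(ratio * n_pos) else check_scalar_int(n, "n")
  zeros <- which(A$values == 0)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    excl_lin <- (as.integer(exclude[, 2L]) - 1L) * nrow(A$values) + as.integer(exclude[, 1L])
    zeros <- setdiff(zeros, excl_lin)
  }
  if (length(zeros) < need) {
    abort(sprintf("Not enough unknown cells to sample %d negatives (have %d).",
                  need, length(zeros)))
  }
  picked <- with_local_seed(derive_seed(seed, "negatives"), {
    sample(zeros, need)
  })
  out <- cbind(
    circ_index = ((picked - 1L) %% nrow(A$values)) + 1L,
    disease_index = ((picked - 1L) %/% nrow(A$values)) + 1L
  )
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

#' Train an association classifier on labelled pair features
#'
#' The default classifier is an extremely-randomized-trees ensemble
#' (extra trees: bagged decision trees with fully random split thresholds),
#' matching the method's reference configuration. Alternative families are
#' provided for classifier-comparison experiments: random forest, logistic
#' regression, k-nearest neighbours, and Gaussian naive Bayes. All produce
#' scores in `[0, 1]` via class-1 probability.
#'
#' @param features Numeric feature matrix (one row per pair).
#' @param labels Binary labels (0/1), both classes present.
#' @param kind One of `"et"`, `"rf"`, `"lr"`, `"knn"`, `"nb"`.
#' @param seed Integer seed.
#' @param num_trees Trees for the ensemble families (default 100).
#' @return Object of class `cda_classifier`.
#' @export
train_classifier <- function(features, labels, kind = c("et", "rf", "lr", "knn", "nb"),
                             seed = 1, num_trees = 100) {
  kind <- match.arg(kind)
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) abort("Both classes must be present for training.")
  if (length(labels) != nrow(features)) abort("Label/feature length mismatch.")
  cseed <- derive_seed(seed, paste0("classifier-", kind))
  fit <- switch(
    kind,
    et = ranger::ranger(
      x = as.data.frame(features), y = factor(labels, levels = c(0, 1)),
      num.trees = num_trees, splitrule = "extratrees", num.random.splits = 1,
      replace = FALSE, sample.fraction = 1, min.node.size = 1,
      probability = TRUE, seed = cseed, num.threads = 1
    ),
    rf = ranger::ranger(
      x = as.data.frame(features), y = factor(labels, levels = c(0, 1)),
      num.trees = num_trees, probability = TRUE, seed = cseed, num.threads = 1
    ),
    lr = {
      df <- as.data.frame(features)
      df$.y <- labels
      suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
    },
    knn = {
      if (!requireNamespace("class", quietly = TRUE)) abort("Package 'class' is required for kind = 'knn'.")
      list(train = features, labels = labels, k = 5L)
    },
    nb = {
      if (!requireNamespace("e1071", quietly = TRUE)) abort("Package 'e1071' is required for kind = 'nb'.")
      e1071::naiveBayes(x = as.data.frame(features), y = factor(labels, levels = c(0, 1)))
    }
  )
  structure(list(kind = kind, fit = fit, seed = cseed, n_features = ncol(features)),
            class = "cda_classifier")
}

#' Score candidate pairs with a trained classifier
#'
#' @param model A `cda_classifier`.
#' @param features Feature matrix with the training-time width.
#' @return Numeric vector of association scores in `[0, 1]`.
#' @export
score_pairs <- function(model, features) {
  stopifnot(inherits(model, "cda_classifier"))
  features <- as.matrix(features)
  if (ncol(features) != model$n_features) {
    abort(sprintf("Feature width %d does not match training width %d.",
                  ncol(features), model$n_features))
  }
  scores <- switch(
    model$kind,
    et = ,
    rf = predict(model$fit, data = as.data.frame(features), num.threads = 1)$predictions[, "1"],
    lr = as.numeric(predict(model$fit, newdata = as.data.frame(features), type = "response")),
    knn = {
      pr <- class::knn(model$fit$train, features,
                       factor(model$fit$labels, levels = c(0, 1)),
                       k = model$fit$k, prob = TRUE)
      votes <- attr(pr, "prob")
      ifelse(pr == "1", votes, 1 - votes)
    },
    nb = predict(model$fit, newdata = as.data.frame(features), type = "raw")[, "1"]
  )
  pmin(pmax(as.numeric(scores), 0), 1)
}

#' @export
print.cda_classifier <- function(x, ...) {
  cat(sprintf("<cda_classifier kind=%s> %d features\n", x$kind, x$n_features))
  invisible(x)
}
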