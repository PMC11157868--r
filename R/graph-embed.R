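#' Symmetrically normalised adjacency with self-loops
#'
#' Computes `D^{-1/2} (X + I) D^{-1/2}` where `D` is the degree matrix of
#' `X + I`. The self-loops guarantee strictly positive degrees, so isolated
#' nodes reduce to a diagonal 1. The result is symmetric with spectral
#' radius at most 1.
#'
#' @param X A square (heterogeneous) adjacency matrix.
#' @return A dense symmetric matrix of the same shape.
#' @export
normalize_adjacency <- function(X) {
  x <- unclass(X)
  if (nrow(x) != ncol(x)) abort("`X` must be square.")
  xt <- x + diag(nrow(x))
  dinv <- 1 / sqrt(rowSums(xt))
  out <- xt * (dinv %o% dinv)
  dimnames(out) <- dimnames(x)
  out
}

#' Local graph embedding by graph-convolutional propagation
#'
#' Propagates the node features `Q` through `depth` layers of
#' `H <- ReLU(A_hat %*% W %*% H)` where `A_hat` is the normalised adjacency
#' of the CDHN and each `W` is a seeded random, untrained
#' `(n+m) x (n+m)` mixing matrix (scaled by `1/sqrt(n+m)`). The result
#' captures the local neighbourhood structure around every node; entries are
#' non-negative by construction.
#'
#' @param X A `heterogeneous_adjacency` (or any square adjacency matrix).
#' @param Q `(n+m) x k` node feature matrix.
#' @param depth Number of propagation layers (default 2).
#' @param seed Seed for the random layer weights.
#' @param weights Optional list of `depth` explicit `(n+m) x (n+m)` layer
#'   weight matrices overriding the seeded random initialisation.
#' @return `(n+m) x k` embedding matrix `H_l` with attribute
#'   `source = "local"`.
#' @export
gcn_embed <- function(X, Q, depth = 2, seed = 1, weights = NULL) {
  x <- unclass(X)
  Q <- as.matrix(Q)
  if (nrow(x) != ncol(x)) abort("`X` must be square.")
  if (nrow(Q) != nrow(x)) {
    abort(sprintf("Feature rows (%d) do not match adjacency size (%d).", nrow(Q), nrow(x)))
  }
  depth <- check_scalar_int(depth, "depth")
  nm <- nrow(x)
  a_hat <- normalize_adjacency(x)
  h <- Q
  ws <- if (is.null(weights)) {
    with_local_seed(derive_seed(seed, "gcn"), {
      lapply(seq_len(depth), function(t) matrix(rnorm(nm * nm) / sqrt(nm), nm, nm))
    })
  } else {
    if (length(weights) != depth) abort("`weights` must supply one matrix per layer.")
    weights
  }
  for (t in seq_len(depth)) {
    h <- pmax(a_hat %*% (ws[[t]] %*% h), 0)
  }
  rownames(h) <- rownames(x)
  attr(h, "source") <- "local"
  h
}

#' Second-order (node2vec) transition probability
#'
#' When a biased random walk sits at node `v` having arrived from node `t`,
#' the probability of stepping to `x` is proportional to
#' `alpha_pq(t, x) * w_vx`, where the bias `alpha` depends on the shortest
#' distance `d_tx` between `t` and `x`: `1/p` for returning (`d = 0`), 1 for
#' staying at distance 1, and `1/q` for moving outward (`d = 2`).
#' Probabilities are normalised over the neighbours of `v`; non-neighbours
#' have probability 0.
#'
#' @param X Adjacency matrix (weights allowed; zero = no edge).
#' @param t,v,x Node identifiers (names of `X`) or indices; the walk arrived
#'   at `v` via the edge `(t, v)`.
#' @param p Return parameter (default 1.0).
#' @param q In-out parameter (default 0.25; values below 1 favour
#'   depth-first, outward exploration).
#' @return The probability of stepping from `v` to `x`.
#' @export
transition_probability <- function(X, t, v, x, p = 1.0, q = 0.25) {
  xm <- unclass(X)
  idx <- function(node) {
    if (is.character(node)) {
      i <- match(node, rownames(xm))
      if (is.na(i)) abort(sprintf("Unknown node: %s", node))
      i
    } else as.integer(node)
  }
  t <- idx(t); v <- idx(v); x <- idx(x)
  if (p <= 0 || q <= 0) abort("`p` and `q` must be positive.")
  if (xm[t, v] == 0) abort("The walk must arrive via an existing edge (t, v).")
  nbrs <- which(xm[v, ] > 0)
  alpha <- function(u) {
    if (u == t) 1 / p else if (xm[t, u] > 0) 1 else 1 / q
  }
  pis <- vapply(nbrs, function(u) alpha(u) * xm[v, u], numeric(1))
  z <- sum(pis)
  if (!(x %in% nbrs)) return(0)
  unname(pis[match(x, nbrs)] / z)
}

#' Walk configuration for the global (node2vec) embedding
#'
#' @param p Return parameter (> 0).
#' @param q In-out parameter (> 0); the default 0.25 biases walks toward
#'   depth-first exploration of the network.
#' @param walk_length Steps per walk.
#' @param num_walks Walks started per (non-isolated) node.
#' @param window Skip-gram context window.
#' @param embed_epochs Skip-gram training epochs over the walk corpus.
#' @param negative Negative samples per positive pair.
#' @param lr Initial skip-gram learning rate (linearly decayed).
#' @export
walk_config <- function(p = 1.0, q = 0.25, walk_length = 80, num_walks = 10,
                        window = 5, embed_epochs = 5, negative = 5, lr = 0.025) {
  if (p <= 0 || q <= 0) abort("`p` and `q` must be positive.")
  list(p = p, q = q,
       walk_length = check_scalar_int(walk_length, "walk_length", 2L),
       num_walks = check_scalar_int(num_walks, "num_walks"),
       window = check_scalar_int(window, "window"),
       embed_epochs = check_scalar_int(embed_epochs, "embed_epochs"),
       negative = check_scalar_int(negative, "negative"),
       lr = lr)
}

#' Simulate biased second-order random walks over a network
#'
#' Starts `num_walks` walks of length `walk_length` from every non-isolated
#' node. The first step is drawn proportionally to edge weight; subsequent
#' steps follow [transition_probability()]. Isolated nodes produce no walks.
#'
#' @param X Adjacency matrix with at least one edge.
#' @param cfg A [walk_config()].
#' @param seed Integer seed; the walk corpus is reproducible.
#' @return List of integer vectors of node indices (attribute `node_ids`
#'   carries the identifier order).
#' @export
simulate_walks <- function(X, cfg = walk_config(), seed = 1) {
  xm <- unclass(X)
  if (nrow(xm) != ncol(xm)) abort("`X` must be square.")
  if (all(xm == 0)) abort("Cannot walk on an edgeless network.")
  nbr <- apply(xm, 1L, function(row) which(row > 0), simplify = FALSE)
  wts <- lapply(seq_len(nrow(xm)), function(i) unname(xm[i, nbr[[i]]]))
  walks <- simulate_walks_cpp(nbr, wts, cfg$p, cfg$q, cfg$num_walks,
                              cfg$walk_length, derive_seed(seed, "walks"))
  attr(walks, "node_ids") <- rownames(xm)
  attr(walks, "n_nodes") <- nrow(xm)
  walks
}

#' Embed a walk corpus with skip-gram negative sampling
#'
#' Learns a `k`-dimensional vector per node from the co-occurrence of nodes
#' within a sliding window over the walks (word2vec-style skip-gram with
#' negative sampling, unigram^0.75 noise distribution, linearly decaying
#' learning rate). Nodes absent from the corpus (isolated nodes) receive
#' zero vectors.
#'
#' @param walks Walk corpus from [simulate_walks()] (or a list of integer
#'   index vectors with attribute `n_nodes`).
#' @param k Embedding width.
#' @param window Context window size.
#' @param epochs Training epochs.
#' @param seed Integer seed.
#' @param negative Negative samples per positive pair.
#' @param lr Initial learning rate.
#' @param n_nodes Number of nodes; defaults to `attr(walks, "n_nodes")`.
#' @return `n_nodes x k` embedding matrix with attribute `source = "global"`.
#' @export
embed_walks <- function(walks, k = 64, window = 5, epochs = 5, seed = 1,
                        negative = 5, lr = 0.025, n_nodes = attr(walks, "n_nodes")) {
  k <- check_scalar_int(k, "k")
  if (is.null(n_nodes)) abort("`n_nodes` is required when walks carry no n_nodes attribute.")
  if (length(walks) == 0L) abort("Empty walk corpus.")
  emb <- sgns_cpp(walks, as.integer(n_nodes), as.integer(k), as.integer(window),
                  as.integer(epochs), as.integer(negative), lr,
                  derive_seed(seed, "sgns"))
  ids <- attr(walks, "node_ids")
  if (!is.null(ids)) rownames(emb) <- ids
  attr(emb, "source") <- "global"
  emb
}

#' Global graph embedding via biased random walks
#'
#' Convenience wrapper: simulate node2vec walks over `X`, then train the
#' skip-gram embedding.
#'
#' @param X Adjacency matrix.
#' @param k Embedding width.
#' @param cfg A [walk_config()].
#' @param seed Integer seed shared by walk simulation and embedding.
#' @return `(n+m) x k` embedding matrix `H_g`.
#' @export
node2vec_embed <- function(X, k = 64, cfg = walk_config(), seed = 1) {
  walks <- simulate_walks(X, cfg, seed = seed)
  embed_walks(walks, k = k, window = cfg$window, epochs = cfg$embed_epochs,
              seed = seed, negative = cfg$negative, lr = cfg$lr)
}
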