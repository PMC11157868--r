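# Independent brute-force oracles used to check the package's closed-form /
# vectorised implementations. These deliberately use naive algorithms
# (explicit path enumeration, per-pair scalar evaluation, pairwise score
# comparison) so they share no code path with the implementation.

# All downward paths in the ontology DAG from ancestor `a` to target `d`;
# the semantic contribution is the max of gamma^length over those paths.
oracle_semantic_contribution <- function(ontology, d, gamma) {
  t_d <- ancestor_set(ontology, d)
  path_lengths <- function(a) {
    if (a == d) return(0L)
    kids <- intersect(ontology$children[[a]], t_d)
    unlist(lapply(kids, function(k) path_lengths(k) + 1L))
  }
  vapply(t_d, function(a) max(gamma^path_lengths(a)), numeric(1))
}

oracle_semantic_similarity <- function(ontology, d1, d2, gamma) {
  sc1 <- oracle_semantic_contribution(ontology, d1, gamma)
  sc2 <- oracle_semantic_contribution(ontology, d2, gamma)
  shared <- intersect(names(sc1), names(sc2))
  num <- if (length(shared) > 0) sum(sc1[shared]) + sum(sc2[shared]) else 0
  num / (sum(sc1) + sum(sc2))
}

# Per-pair scalar evaluation of the Gaussian interaction profile kernel.
oracle_gip <- function(values, axis) {
  profiles <- if (axis == "circrna") values else t(values)
  p <- nrow(profiles)
  lambda <- p / sum(profiles^2)
  k <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      k[i, j] <- exp(-lambda * sum((profiles[i, ] - profiles[j, ])^2))
    }
  }
  k
}

# Second-order transition probability by explicit shortest-distance
# computation (igraph) and normalisation over all nodes.
oracle_transition <- function(adj, t, v, x, p, q) {
  g <- igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected")
  dist_t <- igraph::distances(g, v = t)[1, ]
  pis <- vapply(seq_len(nrow(adj)), function(u) {
    if (adj[v, u] == 0) return(0)
    alpha <- if (dist_t[u] == 0) 1 / p else if (dist_t[u] == 1) 1 else 1 / q
    alpha * adj[v, u]
  }, numeric(1))
  if (sum(pis) == 0) return(0)
  pis[x] / sum(pis)
}

# Pairwise-comparison AUROC: P(score_pos > score_neg) with ties at 1/2.
oracle_auroc <- function(labels, scores) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  total <- 0
  for (a in sp) for (b in sn) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(sp) * length(sn))
}

# Naive AUPR: walk thresholds one prediction at a time (ties grouped),
# accumulate precision x recall-increment.
oracle_aupr <- function(labels, scores) {
  np <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  total <- 0
  for (s in thr) {
    pred <- scores >= s
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / np
    total <- total + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  total
}

oracle_confusion_metrics <- function(labels, scores, threshold) {
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  list(
    accuracy = (tp + tn) / length(labels),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den
  )
}

bare_matrix <- function(x) {
  x <- unclass(as.matrix(x))
  attributes(x) <- list(dim = dim(x))
  x
}

# Small random DAG fixtures for property tests: reuse the package generator's
# ontology (which the loaders must also accept).
random_ontology <- function(n_terms, seed, depth = 4) {
  generate_synthetic_dataset(n = 2, m = n_terms, n_pos = 2, latent_rank = 1,
                             dag_depth = depth, seed = seed)$ontology
}

random_assoc <- function(n, m, n_pos, seed) {
  generate_synthetic_dataset(n = n, m = m, n_pos = n_pos, latent_rank = 2,
                             dag_depth = 3, seed = seed)$associations
}

# Cheap pipeline configuration for fast unit tests (not the study defaults).
tiny_config <- function(k = 8) {
  cda_config(
    k = k, ae_epochs = 40,
    walk = walk_config(walk_length = 20, num_walks = 3, window = 3,
                       embed_epochs = 2),
    num_trees = 50
  )
}
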