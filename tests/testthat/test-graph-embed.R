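path4 <- matrix(0, 4, 4)
path4[cbind(1:3, 2:4)] <- 1
path4 <- path4 + t(path4)

rand_graph <- function(n, seed, p_edge = 0.4) {
  set.seed(seed)
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- as.numeric(runif(n * (n - 1) / 2) < p_edge)
  a + t(a)
}

test_that("adjacency normalisation matches hand-computed cases", {
  expect_equal(normalize_adjacency(matrix(0, 3, 3)), diag(3))

  edge2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(normalize_adjacency(edge2), matrix(0.5, 2, 2))

  for (s in 1:5) {
    a <- rand_graph(8, s)
    nrm <- normalize_adjacency(a)
    expect_true(isSymmetric(nrm))
    expect_lte(max(abs(eigen(nrm, symmetric = TRUE, only.values = TRUE)$values)),
               1 + 1e-9)
  }
})

test_that("GCN propagation is non-negative, seeded, and reduces to ReLU(Q) on empty graphs", {
  a <- rand_graph(10, 1)
  q <- matrix(rnorm(10 * 4), 10, 4)
  h1 <- gcn_embed(a, q, depth = 2, seed = 3)
  h2 <- gcn_embed(a, q, depth = 2, seed = 3)
  expect_identical(h1, h2)
  expect_true(all(h1 >= 0))
  expect_equal(dim(h1), c(10L, 4L))

  hz <- gcn_embed(matrix(0, 10, 10), q, depth = 1, weights = list(diag(10)))
  expect_equal(unname(hz), pmax(q, 0), ignore_attr = TRUE)

  expect_error(gcn_embed(a, matrix(0, 3, 4)), "match")
})

test_that("transition probabilities implement the p/q bias over distances", {
  # t-v edge; v's neighbours: t (d=0), a (d=1, adjacent to t), b (d=2)
  g <- matrix(0, 4, 4, dimnames = rep(list(c("t", "v", "a", "b")), 2))
  g["t", "v"] <- g["v", "t"] <- 1
  g["v", "a"] <- g["a", "v"] <- 1
  g["v", "b"] <- g["b", "v"] <- 1
  g["t", "a"] <- g["a", "t"] <- 1
  probs <- vapply(c("t", "a", "b"), function(x)
    transition_probability(g, "t", "v", x, p = 1.0, q = 0.25), numeric(1))
  expect_equal(unname(probs), c(1, 1, 4) / 6)

  # triangle with p = q = 1: uniform over the two non-trivial neighbours
  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(transition_probability(tri, 1, 2, 3, p = 1, q = 1), 0.5)
  expect_equal(transition_probability(tri, 1, 2, 1, p = 1, q = 1), 0.5)

  # normalisation over all neighbours of v
  s <- sum(vapply(1:4, function(x)
    transition_probability(path4, 1, 2, x, p = 1, q = 0.25), numeric(1)))
  expect_equal(s, 1)

  expect_equal(transition_probability(path4, 1, 2, 4, p = 1, q = 1), 0)
  expect_error(transition_probability(path4, 1, 4, 3), "existing edge")
})

test_that("transition probabilities agree with a shortest-distance oracle", {
  for (s in 1:8) {
    n <- sample(5:12, 1)
    a <- rand_graph(n, s + 100)
    edges <- which(a > 0, arr.ind = TRUE)
    if (nrow(edges) == 0) next
    take <- head(seq_len(nrow(edges)), 6)
    for (e in take) {
      t <- edges[e, 1]; v <- edges[e, 2]
      for (x in seq_len(n)) {
        expect_equal(
          transition_probability(a, t, v, x, p = 2, q = 0.5),
          oracle_transition(a, t, v, x, p = 2, q = 0.5),
          tolerance = 1e-12
        )
      }
    }
  }
})

test_that("walk simulation respects graph structure and seeding", {
  edge2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = rep(list(c("u", "w")), 2))
  walks <- simulate_walks(edge2, walk_config(walk_length = 10, num_walks = 2), seed = 1)
  expect_length(walks, 4L)
  for (wk in walks) {
    expect_true(all(wk == rep_len(c(wk[1], setdiff(1:2, wk[1])), 10)))
  }

  w1 <- simulate_walks(path4, walk_config(walk_length = 15, num_walks = 3), seed = 9)
  w2 <- simulate_walks(path4, walk_config(walk_length = 15, num_walks = 3), seed = 9)
  expect_identical(w1, w2)

  # isolated node produces no walks
  iso <- rbind(cbind(edge2, 0), 0)
  wi <- simulate_walks(unname(iso), walk_config(walk_length = 5, num_walks = 1), seed = 1)
  expect_length(wi, 2L)
  expect_false(any(vapply(wi, function(w) 3 %in% w, logical(1))))

  expect_error(simulate_walks(matrix(0, 3, 3)), "edgeless")
})

test_that("walk embedding yields finite vectors, zero rows for isolated nodes", {
  iso <- matrix(0, 5, 5)
  iso[1, 2] <- iso[2, 1] <- iso[2, 3] <- iso[3, 2] <- 1
  walks <- simulate_walks(iso, walk_config(walk_length = 20, num_walks = 5, window = 3),
                          seed = 2)
  emb <- embed_walks(walks, k = 6, window = 3, epochs = 2, seed = 2)
  expect_equal(dim(emb), c(5L, 6L))
  expect_true(all(is.finite(emb)))
  expect_equal(emb[4, ], rep(0, 6))
  expect_equal(emb[5, ], rep(0, 6))
  expect_true(all(rowSums(abs(emb[1:3, ])) > 0))

  emb2 <- embed_walks(walks, k = 6, window = 3, epochs = 2, seed = 2)
  expect_identical(emb, emb2)
})

test_that("walk embedding separates the two halves of a barbell graph", {
  # two 5-cliques joined by a single bridge edge
  blk <- matrix(1, 5, 5) - diag(5)
  g <- rbind(cbind(blk, matrix(0, 5, 5)), cbind(matrix(0, 5, 5), blk))
  g[5, 6] <- g[6, 5] <- 1
  emb <- node2vec_embed(g, k = 8,
                        cfg = walk_config(walk_length = 30, num_walks = 8,
                                          window = 4, embed_epochs = 4),
                        seed = 11)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  within <- c()
  between <- c()
  for (i in 1:10) for (j in 1:10) {
    if (i >= j) next
    cs <- cosine(emb[i, ], emb[j, ])
    if ((i <= 5) == (j <= 5)) within <- c(within, cs) else between <- c(between, cs)
  }
  expect_gt(mean(within), mean(between))
})
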