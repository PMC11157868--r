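chain <- disease_ontology(tibble::tibble(child = c("b", "a"), parent = c("a", "r")))
diamond <- disease_ontology(tibble::tibble(
  child = c("b", "b", "a1", "a2"), parent = c("a1", "a2", "r", "r")
))

test_that("semantic contribution decays along the DAG with the max rule", {
  sc <- semantic_contribution(chain, "b", gamma = 0.5)
  expect_equal(sc$contributions[c("b", "a", "r")], c(b = 1, a = 0.5, r = 0.25))
  expect_equal(semantic_value(sc), 1.75)

  iso <- disease_ontology(tibble::tibble(child = character(), parent = character()),
                          terms = "d")
  sc_iso <- semantic_contribution(iso, "d", gamma = 0.9)
  expect_equal(sc_iso$contributions, c(d = 1))
  expect_equal(semantic_value(sc_iso), 1)

  # diamond: both length-2 downward paths from the root give 0.25
  sc_d <- semantic_contribution(diamond, "b", gamma = 0.5)
  expect_equal(sc_d$contributions[["r"]], 0.25)
  expect_equal(semantic_value(sc_d), 2.25)

  expect_error(semantic_contribution(chain, "zzz"), "Unknown")
})

test_that("disease semantic similarity matches the shared-ancestor formula", {
  ds <- disease_semantic_similarity(chain, c("a", "b", "r"), gamma = 0.5)
  expect_equal(unname(diag(ds)), rep(1, 3))
  expect_equal(ds["a", "b"], 2.25 / 3.25, tolerance = 1e-15)
  expect_true(isSymmetric(bare_matrix(ds)))

  # disjoint ancestor sets give zero
  two <- disease_ontology(tibble::tibble(child = c("x", "y"), parent = c("px", "py")))
  ds2 <- disease_semantic_similarity(two, c("x", "y"))
  expect_equal(ds2["x", "y"], 0)
})

test_that("diseases absent from the ontology fall back to T_d = {d} with warning", {
  expect_warning(
    ds <- disease_semantic_similarity(chain, c("a", "nope")),
    "absent"
  )
  expect_equal(ds["nope", "nope"], 1)
  expect_equal(ds["a", "nope"], 0)
})

test_that("semantic machinery agrees with brute-force path enumeration", {
  for (s in 1:30) {
    ont <- random_ontology(n_terms = sample(5:20, 1), seed = s)
    gamma <- 0.5
    d <- sample(ont$terms, 1)
    sc <- semantic_contribution(ont, d, gamma)$contributions
    oracle <- oracle_semantic_contribution(ont, d, gamma)
    expect_equal(sc[sort(names(sc))], oracle[sort(names(oracle))], tolerance = 1e-12)
  }
})

test_that("circRNA functional similarity is a best-match average over disease sets", {
  ds <- disease_semantic_similarity(chain, c("a", "b", "r"))
  # identical nonempty disease sets -> similarity 1
  a1 <- as_association_matrix(tibble::tibble(c = c("c1", "c2"), d = c("a", "a")))
  fs1 <- circrna_functional_similarity(a1, ds)
  expect_equal(unname(fs1), matrix(1, 2, 2), ignore_attr = TRUE)

  # an empty disease set zeroes the row including the diagonal
  a2 <- new_association_matrix(matrix(c(1, 0), 2, 1), c("c1", "c2"), "a")
  fs2 <- circrna_functional_similarity(a2, ds)
  expect_equal(unname(fs2[2, ]), c(0, 0))
  expect_equal(fs2["c1", "c1"], 1)

  # cross-set case from the chain DAG: T_i = {a}, T_j = {b}
  a3 <- new_association_matrix(matrix(c(1, 0, 0, 1), 2, 2), c("c1", "c2"), c("a", "b"))
  fs3 <- circrna_functional_similarity(a3, ds)
  expect_equal(fs3["c1", "c2"], 2.25 / 3.25, tolerance = 1e-12)
  expect_true(isSymmetric(bare_matrix(fs3)))
})

test_that("GIP kernel matches hand evaluation and the scalar oracle", {
  a <- new_association_matrix(diag(2), c("c1", "c2"), c("d1", "d2"))
  ck <- gip_kernel(a, "circrna")
  expect_equal(unname(diag(ck)), c(1, 1))
  expect_equal(ck["c1", "c2"], exp(-2), tolerance = 1e-15)

  same <- new_association_matrix(matrix(1, 2, 2), c("c1", "c2"), c("d1", "d2"))
  expect_equal(unname(gip_kernel(same, "circrna")), matrix(1, 2, 2), ignore_attr = TRUE)

  for (s in 1:10) {
    am <- random_assoc(n = sample(5:20, 1), m = sample(3:10, 1), n_pos = 10, seed = s)
    for (axis in c("circrna", "disease")) {
      k <- gip_kernel(am, axis)
      expect_equal(unname(unclass(k)), oracle_gip(am$values, axis), tolerance = 1e-12, ignore_attr = TRUE)
      expect_true(all(k > 0 & k <= 1))
    }
  }

  zero <- new_association_matrix(matrix(0, 2, 2), c("c1", "c2"), c("d1", "d2"))
  expect_error(gip_kernel(zero), "all-zero")
})

test_that("similarity integration keeps primary where nonzero, else fallback", {
  p <- matrix(c(1, 0, 0, 1), 2, 2)
  f <- matrix(c(1, 0.2, 0.2, 1), 2, 2)
  expect_equal(unclass(integrate_similarity(p, f)), f, ignore_attr = TRUE)
  expect_equal(unclass(integrate_similarity(f, p)), f, ignore_attr = TRUE)
  expect_equal(unclass(integrate_similarity(matrix(0, 2, 2), f)), f, ignore_attr = TRUE)

  # idempotent under a second application with the same fallback
  once <- integrate_similarity(p, f)
  expect_equal(unclass(integrate_similarity(once, f)), unclass(once), ignore_attr = TRUE)

  expect_error(integrate_similarity(p, matrix(0, 3, 3)), "Shape")
})

test_that("heterogeneous adjacency has the block structure of the bipartite graph", {
  a <- new_association_matrix(matrix(1, 2, 1), c("c1", "c2"), "d1")
  x <- build_heterogeneous_adjacency(a)
  expect_equal(dim(x), c(3L, 3L))
  expect_equal(unname(unclass(x)),
               matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3, 3), ignore_attr = TRUE)

  az <- new_association_matrix(matrix(0, 2, 2), c("c1", "c2"), c("d1", "d2"))
  expect_true(all(unclass(build_heterogeneous_adjacency(az)) == 0))

  am <- random_assoc(8, 4, 10, seed = 2)
  xm <- bare_matrix(build_heterogeneous_adjacency(am))
  expect_true(isSymmetric(xm))
  expect_equal(sum(diag(xm)), 0)
  expect_true(all(xm[1:8, 1:8] == 0))
  expect_true(all(xm[9:12, 9:12] == 0))
})
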