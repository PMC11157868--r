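test_that("association matrix collapses duplicates and orders ids deterministically", {
  pairs <- tibble::tibble(circrna = c("c1", "c2", "c1"), disease = c("d1", "d1", "d1"))
  a <- as_association_matrix(pairs)
  expect_equal(dim(a$values), c(2L, 1L))
  expect_true(all(a$values == 1))

  b <- as_association_matrix(tibble::tibble(c = c("c2", "c1"), d = c("d2", "d1")))
  expect_equal(b$circ_ids, c("c1", "c2"))
  expect_equal(b$disease_ids, c("d1", "d2"))
  expect_equal(unname(b$values), diag(2))
})

test_that("association list reading validates input and round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("circrna\tdisease", "c2\td1", "c1\td2", "c1\td2"), f)
  a <- read_association_list(f)
  expect_equal(sum(a$values), 2)

  # round trip through write + read reproduces the matrix exactly
  g <- withr::local_tempfile(fileext = ".tsv")
  write_association_list(a, g)
  expect_equal(read_association_list(g), a)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_error(read_association_list(empty), "Empty|malformed")

  one_col <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1", "c2"), one_col)
  expect_error(read_association_list(one_col), "malformed")
})

test_that("exclusion list removes curated pairs before matrix construction", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1\td1", "c2\td1", "c2\td2"), f)
  ex <- withr::local_tempfile(fileext = ".tsv")
  writeLines("c2\td2", ex)
  a <- read_association_list(f, exclude = ex)
  expect_equal(sum(a$values), 2)
  expect_equal(a$disease_ids, "d1")
})

test_that("ontology construction validates DAG structure", {
  chain <- disease_ontology(tibble::tibble(child = c("b", "a"), parent = c("a", "r")))
  expect_setequal(chain$terms, c("a", "b", "r"))
  expect_equal(ancestor_set(chain, "b"), c("a", "b", "r"))

  expect_error(
    disease_ontology(tibble::tibble(child = c("a", "b"), parent = c("b", "a"))),
    "cycle"
  )
  expect_error(
    disease_ontology(tibble::tibble(child = "a", parent = "a")),
    "Self-loop"
  )

  iso <- disease_ontology(tibble::tibble(child = character(), parent = character()),
                          terms = letters[1:5])
  expect_equal(length(iso$terms), 5L)
  for (tm in iso$terms) expect_equal(ancestor_set(iso, tm), tm)
})

test_that("ontology loader reads files and accepts generator output", {
  fx <- generate_synthetic_dataset(n = 5, m = 12, n_pos = 10, latent_rank = 2,
                                   dag_depth = 4, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_disease_ontology(fx$ontology, f)
  reread <- read_disease_ontology(f, terms = fx$ontology$terms)
  expect_equal(reread$terms, fx$ontology$terms)
  for (tm in fx$ontology$terms) {
    expect_equal(ancestor_set(reread, tm), ancestor_set(fx$ontology, tm))
  }
})

test_that("synthetic generator plants the requested structure reproducibly", {
  fx <- generate_synthetic_dataset(n = 10, m = 5, n_pos = 8, latent_rank = 2,
                                   dag_depth = 3, seed = 0)
  expect_equal(sum(fx$associations$values), 8)
  expect_equal(dim(fx$associations$values), c(10L, 5L))

  fx2 <- generate_synthetic_dataset(n = 10, m = 5, n_pos = 8, latent_rank = 2,
                                    dag_depth = 3, seed = 0)
  expect_identical(fx, fx2)

  fx3 <- generate_synthetic_dataset(n = 100, m = 30, n_pos = 300, latent_rank = 3,
                                    dag_depth = 4, seed = 1)
  expect_equal(mean(fx3$associations$values), 0.1)
  expect_error(generate_synthetic_dataset(n = 2, m = 2, n_pos = 5, latent_rank = 1,
                                          dag_depth = 2, seed = 1),
               "exceed")
})

test_that("score files are sorted with deterministic tie-breaking", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scores(tibble::tibble(circrna = c("c2", "c1"), disease = "d1",
                              score = c(0.9, 0.9)), f)
  lines <- readLines(f)
  expect_match(lines[2], "^c1\t")
  expect_match(lines[3], "^c2\t")

  write_scores(tibble::tibble(circrna = c("c1", "c2"), disease = "d1",
                              score = c(0.2, 0.8)), f)
  expect_match(readLines(f)[2], "^c2\t")

  write_scores(tibble::tibble(circrna = character(), disease = character(),
                              score = numeric()), f)
  expect_length(readLines(f), 1L)

  expect_error(write_scores(tibble::tibble(circrna = "c", disease = "d", score = 1.2), f),
               "\\[0, 1\\]")
})

test_that("similarity matrices round-trip through dense TSV and MTX", {
  a <- random_assoc(8, 5, 10, seed = 13)
  ck <- gip_kernel(a, "circrna")

  f <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_matrix(ck, f)
  back <- read_similarity_matrix(f)
  expect_equal(back, unclass(ck), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rownames(back), a$circ_ids)

  g <- withr::local_tempfile(fileext = ".mtx")
  write_similarity_matrix(unclass(a$values), g)
  back2 <- read_similarity_matrix(g)
  expect_equal(unname(back2), unname(a$values), ignore_attr = TRUE)
  expect_equal(rownames(back2), a$circ_ids)
})

test_that("the command-line wrapper drives the pipeline end to end", {
  cli <- system.file("cli", "circlink.R", package = "circlink")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  out <- system2("Rscript", c(cli, "simulate", "--n", "15", "--m", "8",
                              "--n-pos", "25", "--seed", "3",
                              "--out-dir", dir),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "associations.tsv")))
  expect_true(file.exists(file.path(dir, "ontology.tsv")))

  out2 <- system2("Rscript", c(cli, "build-net",
                               "--associations", file.path(dir, "associations.tsv"),
                               "--ontology", file.path(dir, "ontology.tsv"),
                               "--out-dir", file.path(dir, "nets")),
                  stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "nets", "Xc.tsv")))
  # the pair-list format only carries circRNAs with >= 1 association
  reread <- read_association_list(file.path(dir, "associations.tsv"))
  xc <- read_similarity_matrix(file.path(dir, "nets", "Xc.tsv"))
  expect_equal(dim(xc), rep(length(reread$circ_ids), 2))
  expect_true(all(diag(xc) == 1))
})
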