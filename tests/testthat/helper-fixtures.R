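# Shared fixtures, built lazily and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

tiny_spec <- function(seed = 42) {
  synthetic_spec(m = 8, n_drugs = 5, d_genes = 20, k = 2, image_size = 32,
                 seed = seed)
}

tiny_dataset <- function() memo("tiny_dataset", generate_dataset(tiny_spec()))

tiny_config <- function(epochs = 5, folds = 2, ...) {
  model_config(f = 4, epochs = epochs, folds = folds, seed = 42,
               image_size = 32, ...)
}

tiny_encoded <- function() {
  memo("tiny_encoded", encode_dataset(tiny_dataset(), tiny_config()))
}

# frozen per-atom feature vectors computed with an independent
# cheminformatics toolkit implementing the same ConvMol layout
convmol_oracle <- function() {
  memo("convmol_oracle",
       jsonlite::read_json(test_path("rdkit_convmol_features.json"),
                           simplifyVector = TRUE))
}

# the packaged drug library, featurized once
library_graphs <- function(n = 68) {
  memo(paste0("library_graphs_", n), packaged_drug_graphs(n))
}

# random small parameter set for head/drug-encoder tests
fixed_drug_params <- function(f = 4, seed = 7) {
  set.seed(seed)
  list(G1 = matrix(rnorm(75 * 2 * f, sd = 0.2), 75, 2 * f),
       G2 = matrix(rnorm(2 * f * 2 * f, sd = 0.2), 2 * f, 2 * f))
}

random_adjacency <- function(n, p = 0.4) {
  A <- matrix(rbinom(n * n, 1, p), n, n)
  A[lower.tri(A, diag = TRUE)] <- 0
  A + t(A)
}
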