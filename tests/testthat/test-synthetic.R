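test_that("generation is bit-reproducible from the spec seed", {
  spec <- tiny_spec(seed = 7)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(serialize(d1, NULL), serialize(d2, NULL))
  d3 <- generate_dataset(tiny_spec(seed = 8))
  expect_false(identical(d1$latents$U, d3$latents$U))
})

test_that("emitted IC50/threshold pairs reproduce the generator labels", {
  ds <- tiny_dataset()
  rec <- ds$response$records
  relab <- binarize_response(rec$ic50, rec$max_screening_conc)
  expect_identical(relab, rec$label)
})

test_that("generated inputs have the declared shapes and survive preprocessing", {
  spec <- tiny_spec()
  ds <- tiny_dataset()
  expect_identical(dim(ds$expr$values), c(spec$m, spec$d_genes))
  expect_identical(dim(ds$cnv$values), c(spec$m, spec$d_genes))
  expect_length(ds$images, spec$m)
  expect_length(ds$graphs, spec$n_drugs)
  expect_true(all(ds$expr$values >= 0))   # TPM-scale, log-transformable
  for (im in ds$images[1:3]) {
    again <- preprocess_image(im$pixels, size = spec$image_size)
    expect_equal(again$pixels, im$pixels)   # already standardized
  }
  enc <- tiny_encoded()
  expect_true(all(abs(colMeans(enc$Xe)) < 1e-6))
  expect_true(all(abs(colMeans(enc$Xc)) < 1e-6))
})

test_that("the planted latents separate the labels near-perfectly", {
  spec <- synthetic_spec(m = 30, n_drugs = 20, d_genes = 30, noise_sd = 0,
                         image_size = 32, seed = 5)
  ds <- generate_dataset(spec)
  U <- ds$latents$U
  V <- ds$latents$V
  rec <- ds$response$records
  ci <- match(rec$cell_line, ds$cell_ids)
  dj <- match(rec$drug, ds$drug_ids)
  feats <- U[ci, , drop = FALSE] * V[dj, , drop = FALSE]
  fit <- suppressWarnings(glm.fit(cbind(1, feats), rec$label,
                                  family = binomial()))
  sc <- drop(cbind(1, feats) %*% fit$coefficients)
  expect_gte(compute_metrics(sc, rec$label)$auc, 0.99)
})

test_that("more observation noise degrades factor recovery from omics", {
  r2 <- sapply(c(0.1, 2, 8), function(ns) {
    spec <- synthetic_spec(m = 40, n_drugs = 5, d_genes = 60, noise_sd = ns,
                           image_size = 32, seed = 9)
    ds <- generate_dataset(spec)
    enc <- encode_dataset(ds, tiny_config())
    X <- cbind(enc$Xe, enc$Xc)
    U <- ds$latents$U[, 3:6]   # the factors the omics views observe
    # ridge probe of the latent factors from observed omics
    W <- qr.solve(crossprod(X) + 10 * diag(ncol(X)), crossprod(X, U))
    Uhat <- X %*% W
    1 - sum((Uhat - U)^2) / sum(scale(U, scale = FALSE)^2)
  })
  expect_true(all(diff(r2) < 0))
})

test_that("class balance and table density are calibrated", {
  spec <- synthetic_spec(m = 40, n_drugs = 30, d_genes = 30, image_size = 32,
                         sensitive_fraction = 0.35, density = 0.6, seed = 3)
  ds <- generate_dataset(spec)
  rec <- ds$response$records
  expect_lt(abs(mean(rec$label) - 0.35), 0.08)
  expect_lt(abs(nrow(rec) / (40 * 30) - 0.6), 0.08)
  # coverage: every cell line and drug keeps at least one record
  expect_setequal(unique(rec$cell_line), ds$cell_ids)
  expect_setequal(unique(rec$drug), ds$drug_ids)
  expect_error(generate_dataset(synthetic_spec(sensitive_fraction = 1.2)),
               "sensitive_fraction")
})

test_that("datasets round-trip through the on-disk layout", {
  ds <- tiny_dataset()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir, c("expression.csv", "cnv.csv",
                                               "drugs.csv", "response.csv")))))
  back <- suppressMessages(load_dataset(dir, image_size = 32))
  expect_identical(back$cell_ids, ds$cell_ids)
  expect_identical(back$drug_ids, ds$drug_ids)
  expect_identical(back$response$records$label, ds$response$records$label)
  expect_equal(back$expr$values, ds$expr$values, tolerance = 1e-6)
  # PNG quantization only
  expect_lt(max(abs(back$images[[1]]$pixels - ds$images[[1]]$pixels)), 1 / 255)
})

test_that("the worked example exposes consistent intermediates", {
  ex <- suppressMessages(make_worked_example())
  expect_identical(length(ex$dataset$cell_ids), 4L)
  expect_identical(length(ex$dataset$drug_ids), 3L)
  expect_lte(nrow(ex$dataset$response$records), 12)
  expect_true(all(abs(rowSums(ex$attention) - 1) < 1e-6))
  for (Ah in ex$adjacency) {
    expect_equal(Ah, t(Ah))
    expect_true(all(Ah >= 0 & Ah <= 1))
  }
  expect_true(all(ex$probabilities > 0 & ex$probabilities < 1))
  ref <- withr::local_tempfile(fileext = ".txt")
  suppressMessages(make_worked_example(reference_file = ref))
  expect_true(file.exists(ref))
  expect_gt(file.size(ref), 200)
})
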