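test_that("the prediction head is a sigmoid MLP on the 4f concatenation", {
  f <- 18
  zero_head <- list(H1 = matrix(0, 4 * f, 2 * f), h1b = numeric(2 * f),
                    H2 = matrix(0, 2 * f, 1), h2b = 0)
  expect_equal(predict_pair(rnorm(2 * f), rnorm(2 * f), zero_head), 0.5)

  set.seed(1)
  head <- list(H1 = matrix(rnorm(4 * f * 2 * f, sd = 0.1), 4 * f, 2 * f),
               h1b = rnorm(2 * f), H2 = matrix(rnorm(2 * f), 2 * f, 1),
               h2b = 0.3)
  p <- predict_pair(matrix(rnorm(5 * 2 * f), 5), matrix(rnorm(5 * 2 * f), 5),
                    head)
  expect_length(p, 5)
  expect_true(all(p > 0 & p < 1))
  expect_error(predict_pair(rnorm(10), rnorm(10), head), "head expects 72")
})

test_that("ranking metrics match hand values and the O(n^2) oracle", {
  perfect <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$aupr, 1)
  expect_equal(compute_metrics(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$auc, 0.75)
  expect_equal(compute_metrics(rep(0.4, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(compute_metrics(c(0.1, 0.2), c(1, 1)), "both classes")

  # brute-force concordant-pair count with half-credit ties
  set.seed(2)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    sc <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # forces ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    pos <- sc[y == 1]; neg <- sc[y == 0]
    brute <- 0
    for (a in pos) brute <- brute + sum(a > neg) + 0.5 * sum(a == neg)
    brute <- brute / (length(pos) * length(neg))
    expect_equal(compute_metrics(sc, y)$auc, brute, tolerance = 1e-10)
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  sc <- runif(150)
  y <- rbinom(150, 1, plogis(3 * (sc - 0.5)))
  ref <- as.numeric(suppressMessages(pROC::auc(y, sc)))
  expect_equal(compute_metrics(sc, y)$auc, ref, tolerance = 1e-10)
})

test_that("stratified folds partition pairs evenly and reproducibly", {
  set.seed(4)
  y <- rbinom(203, 1, 0.35)
  f1 <- make_folds(y, 10, seed = 9)
  f2 <- make_folds(y, 10, seed = 9)
  expect_identical(f1, f2)
  expect_true(all(f1 %in% 1:10))
  sizes <- tabulate(f1, 10)
  expect_lte(max(sizes) - min(sizes), 1)
  for (k in 1:10) expect_length(unique(y[f1 == k]), 2)
  expect_false(identical(f1, make_folds(y, 10, seed = 10)))
})

test_that("training is seed-deterministic and decreases the loss", {
  enc <- tiny_encoded()
  cfg <- tiny_config(epochs = 40)
  m1 <- train_model(enc, cfg)
  m2 <- train_model(enc, cfg)
  expect_identical(m1$params, m2$params)   # bit-identical on CPU
  expect_lt(m1$log$L[40], m1$log$L[1])     # descent on the planted signal
  expect_true(all(is.finite(m1$log$L)))
})

test_that("disabling the contrastive term makes training gamma-independent", {
  enc <- tiny_encoded()
  a <- train_model(enc, tiny_config(epochs = 8, ablation = "no_cl"))
  b <- train_model(enc, tiny_config(epochs = 8, ablation = "no_cl",
                                    gamma = 0.5))
  expect_identical(a$params, b$params)
  expect_true(all(a$log$L_cl == 0))
})

test_that("cross-validation covers every pair exactly once", {
  enc <- tiny_encoded()
  rep <- cross_validate(enc, tiny_config(epochs = 5, folds = 2))
  expect_s3_class(rep, "cdr_eval_report")
  expect_identical(nrow(rep$per_fold), 2L)
  expect_identical(nrow(rep$predictions), nrow(enc$pairs))
  expect_true(all(rep$per_fold$auc >= 0 & rep$per_fold$auc <= 1))
  expect_true(all(rep$per_fold$aupr >= 0 & rep$per_fold$aupr <= 1))
  expect_equal(rep$mean_auc, mean(rep$per_fold$auc))
  # each pair appears in exactly one test fold
  key <- paste(rep$predictions$cell_line, rep$predictions$drug)
  expect_identical(anyDuplicated(key), 0L)
})

test_that("the ablation grid shares folds and validates variant names", {
  enc <- tiny_encoded()
  cfg <- tiny_config(epochs = 4, folds = 2)
  tab <- run_ablation(enc, cfg, variants = c("no_cl", "no_image"))
  expect_identical(tab$summary$variant, c("full", "no_cl", "no_image"))
  expect_identical(tab$reports$full$folds, tab$reports$no_cl$folds)
  expect_error(run_ablation(enc, cfg, variants = "no_everything"), "unknown")
})

test_that("checkpoints round-trip through save and load", {
  enc <- tiny_encoded()
  mod <- train_model(enc, tiny_config(epochs = 3))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(mod, path)
  back <- load_model(path)
  expect_identical(back$params, mod$params)
  p1 <- predict(mod, enc)
  p2 <- predict(back, enc)
  expect_identical(p1, p2)
})

test_that("embedding export returns labeled 2f-wide matrices", {
  enc <- tiny_encoded()
  mod <- train_model(enc, tiny_config(epochs = 3))
  emb <- export_embeddings(mod, enc)
  expect_identical(dim(emb$cell), c(enc$m, 8L))
  expect_identical(dim(emb$drug), c(enc$n_drugs, 8L))
  expect_identical(rownames(emb$cell), enc$cell_ids)
  expect_identical(rownames(emb$drug), enc$drug_ids)
})
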