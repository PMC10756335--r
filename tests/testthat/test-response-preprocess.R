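test_that("IC50 binarization uses an inclusive threshold on a shared scale", {
  # the published worked case: 566.28 uM far above a 32 uM screening cap
  expect_identical(binarize_response(566.28, 32), 0L)
  expect_identical(binarize_response(32, 32), 1L)   # boundary is sensitive
  expect_identical(binarize_response(0, 32), 1L)
  expect_identical(binarize_response(c(1, 31.99, 32.01), rep(32, 3)),
                   c(1L, 1L, 0L))
  expect_error(binarize_response(-1, 32), "negative IC50")
  expect_error(binarize_response(NaN, 32, record = "A498/5-FU"), "A498/5-FU")
  expect_error(binarize_response(1, 0), "> 0")
})

test_that("binarization is monotone non-increasing in IC50", {
  set.seed(1)
  thr <- runif(50, 0.1, 100)
  ic <- sort(runif(50, 0, 200))
  for (t in thr[1:5]) {
    labs <- binarize_response(ic, rep(t, length(ic)))
    expect_true(all(diff(labs) <= 0))
  }
})

test_that("response tables reject duplicates and tally labels exactly", {
  rt <- response_table(cell_line = c("c1", "c1", "c2"),
                       drug = c("d1", "d2", "d1"),
                       ic50 = c(1, 100, 40),
                       max_screening_conc = c(32, 32, 32))
  A <- rt$label_matrix
  expect_identical(dim(A), c(2L, 2L))
  expect_identical(A["c1", "d1"], 1L)
  expect_identical(A["c1", "d2"], 0L)
  expect_true(is.na(A["c2", "d2"]))   # unmeasured pair stays missing
  expect_equal(sum(A == 1, na.rm = TRUE) + sum(A == 0, na.rm = TRUE),
               nrow(rt$records))
  expect_error(
    response_table(c("c1", "c1"), c("d1", "d1"), c(1, 2), c(32, 32)),
    "duplicate")
})

test_that("ln-scale comparison gives the same labels as the raw scale", {
  set.seed(2)
  ic <- 10^runif(200, -3, 3)
  thr <- rep(10^runif(10, -1, 2), each = 20)
  raw <- response_table(paste0("c", 1:200), rep("d", 200), ic, thr)
  logd <- response_table(paste0("c", 1:200), rep("d", 200), ic, thr,
                         ic50_scale = "ln")
  expect_identical(raw$records$label, logd$records$label)
})

test_that("log-TPM transform is log2(x+1) and rejects negatives", {
  expect_equal(log_tpm_transform(matrix(c(0, 1, 7))), matrix(c(0, 1, 3)))
  om <- omics_matrix(matrix(c(0, 3, 15, 1), 2), state = "raw")
  out <- log_tpm_transform(om)
  expect_equal(out$state, "log_tpm")
  expect_equal(out$values, matrix(c(0, 2, 4, 1), 2),
               ignore_attr = TRUE)
  expect_error(log_tpm_transform(matrix(c(1, -2))), "non-negative")
})

test_that("gaussian normalization is population z-scoring with a zero-variance guard", {
  out <- gaussian_normalize(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(drop(out), c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_equal(drop(gaussian_normalize(matrix(c(5, 5, 5), ncol = 1))),
               c(0, 0, 0))
  set.seed(3)
  x <- matrix(rnorm(200, sd = 4, mean = 7), 20)
  z <- gaussian_normalize(x)
  expect_true(all(abs(colMeans(z)) < 1e-6))
  expect_true(all(abs(sqrt(colSums(z^2) / nrow(z)) - 1) < 1e-6))
  # idempotence
  expect_equal(gaussian_normalize(z), z, tolerance = 1e-6)
})

test_that("zero-fill replaces only missing entries, bit-exactly", {
  x <- matrix(c(1, NA, NA, 4), 2)
  expect_equal(fill_missing(x), matrix(c(1, 0, 0, 4), 2))
  set.seed(4)
  y <- matrix(runif(50), 10)
  y[sample(50, 12)] <- NA
  obs <- !is.na(y)
  filled <- fill_missing(y)
  expect_identical(filled[obs], y[obs])   # observed entries untouched
  expect_true(all(filled[!obs] == 0))
  expect_identical(fill_missing(y * 0 + NA)[, 1], rep(0, 10))
  expect_equal(fill_missing(matrix(1:4, 2)), matrix(1:4, 2))
})

test_that("image standardization resizes, rescales and fixes channels", {
  set.seed(5)
  big <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  im <- preprocess_image(big, cell_id = "x", size = 32)
  expect_identical(dim(im$pixels), c(32L, 32L, 3L))
  expect_true(all(im$pixels >= 0 & im$pixels <= 1))

  white <- array(1, dim = c(10, 10, 3))
  expect_true(all(preprocess_image(white, size = 32)$pixels == 1))

  sized <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  expect_equal(preprocess_image(sized, size = 32)$pixels, sized)

  gray <- matrix(runif(32 * 32), 32)
  g <- preprocess_image(gray, size = 32)
  expect_identical(dim(g$pixels), c(32L, 32L, 3L))
  expect_equal(g$pixels[, , 1], g$pixels[, , 3])

  eightbit <- array(sample(0:255, 32 * 32 * 3, TRUE), dim = c(32, 32, 3))
  expect_true(max(preprocess_image(eightbit, size = 32)$pixels) <= 1)

  expect_error(preprocess_image(file.path(tempdir(), "nope.png")),
               "not found")
})

test_that("images round-trip through PNG files", {
  px <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  path <- withr::local_tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(px, colormode = "Color"), path)
  im <- preprocess_image(path, size = 32)
  expect_identical(im$cell_id, sub("\\.png$", "", basename(path)))
  expect_identical(dim(im$pixels), c(32L, 32L, 3L))
  # 8-bit quantization on write
  expect_lt(max(abs(im$pixels - px)), 1 / 255)
})
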