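# Synthetic multimodal drug-response data with a planted low-rank signal.
#
# A k-factor latent vector u_i per cell line drives all three views
# (defaults, k = 6):
#   - images observe the leading factors 1..3 through per-channel mean
#     intensity
#   - expression observes factors 2..5, CNV factors {1,5,6}; the
#     image-covered factors enter the omics only as weak echoes, so the
#     image is the clean carrier of the dominant factors while the omics
#     jointly span the image code (keeps the contrastive alignment
#     satisfiable) and each omics view keeps a factor the others lack
# Drug latents v_j pair with u_i: the sensitivity probability is
# sigmoid(logit_scale * standardized(u_i . v_j) + intercept), the intercept
# calibrated to the target sensitive fraction; labels are Bernoulli draws
# converted to IC50 / max-screening-concentration pairs consistent with the
# inclusive binarization rule.

#' Specification of a synthetic dataset
#'
#' @param m Number of cell lines.
#' @param n_drugs Number of drugs (drawn from the packaged SMILES library).
#' @param d_genes Genes per omics matrix.
#' @param k Latent factors (>= 6 recommended so each modality keeps a
#'   private factor; `k <= min(m, d_genes)`).
#' @param noise_sd Observation noise on the omics views, in units of the
#'   (unit-variance) latent signal.
#' @param signal_modality Which views carry the planted signal: `"both"`,
#'   `"omics"` or `"image"` (the silent views become pure noise).
#' @param sensitive_fraction Target fraction of sensitive labels in (0, 1).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the spec.
#' @param image_size Image side length in pixels.
#' @param logit_scale Sharpness of the label probabilities (larger =>
#'   less label noise).
#' @param density Fraction of (cell line, drug) pairs with a measured
#'   response, emulating the incompleteness of real screening tables;
#'   unmeasured pairs are absent from the response table.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(m = 60L, n_drugs = 40L, d_genes = 200L, k = 6L,
                           noise_sd = 0.35, signal_modality = c("both", "omics",
                                                             "image"),
                           sensitive_fraction = 0.5, seed = 1L,
                           image_size = 224L, logit_scale = 12,
                           density = 1) {
  signal_modality <- match.arg(signal_modality)
  cdr_assert(m >= 1 && n_drugs >= 1 && d_genes >= 1 && k >= 1,
             "all sizes must be >= 1")
  cdr_assert(k <= min(m, d_genes), "k must be <= min(m, d_genes)")
  cdr_assert(sensitive_fraction > 0 && sensitive_fraction < 1,
             "sensitive_fraction must be in (0, 1)")
  cdr_assert(density > 0 && density <= 1, "density must be in (0, 1]")
  structure(list(m = as.integer(m), n_drugs = as.integer(n_drugs),
                 d_genes = as.integer(d_genes), k = as.integer(k),
                 noise_sd = noise_sd, signal_modality = signal_modality,
                 sensitive_fraction = sensitive_fraction,
                 seed = as.integer(seed), image_size = as.integer(image_size),
                 logit_scale = logit_scale, density = density),
            class = "synthetic_spec")
}

# Factor windows per view. The image observes the leading factors; the two
# omics views jointly cover all factors, including weak echoes of the
# image factors, so (i) the omics<->image contrastive alignment is
# satisfiable (the shared subspace spans the full image code) and (ii)
# each omics view keeps a factor the others lack. The image's value is
# that it measures the dominant factors cleanly where the omics echoes
# are weak and noise-limited.
# k = 6 gives image {1,2,3}, expression {2,3,4,5}, CNV {1,5,6}.
factor_sets <- function(k) {
  if (k >= 6) {
    list(image = 1:3, expr = 2:(k - 1), cnv = c(1L, (k - 1):k))
  } else {
    a <- ceiling(k / 2)
    b <- ceiling(3 * k / 4)
    list(image = 1:a, expr = a:b, cnv = unique(c(1L, b:k)))
  }
}

# loading strength per factor within an omics view: image-covered factors
# appear only as weak echoes
omics_loading_weights <- function(factors, image_factors, echo = 0.45) {
  ifelse(factors %in% image_factors, echo, 1)
}

#' Generate a synthetic multimodal drug-response dataset
#'
#' See the module comment at the top of the source file for the planted
#' structure. Bit-reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A [cdr_dataset()] whose `latents` field holds the ground truth
#'   (`U`, `V`, pairwise latent `score`, label probabilities `prob`).
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  cdr_assert(inherits(spec, "synthetic_spec"), "spec must be a synthetic_spec")
  set.seed(spec$seed)
  m <- spec$m
  d <- spec$d_genes
  k <- spec$k
  fs <- factor_sets(k)
  cell_ids <- sprintf("CL%03d", seq_len(m))

  U <- matrix(stats::rnorm(m * k), m, k)
  graphs <- packaged_drug_graphs(spec$n_drugs)
  V <- teacher_drug_latents(graphs, k)

  omics_on <- spec$signal_modality %in% c("both", "omics")
  image_on <- spec$signal_modality %in% c("both", "image")

  # Omics noise is mostly low-rank "nuisance" structure (batch effects,
  # co-regulated modules) plus a small iid component, mimicking the strong
  # gene-gene correlation of real panels. Keeping the iid part small keeps
  # the observed matrices near-low-rank, like PCA spectra of real omics.
  nuis_rank <- 4L
  omics_view <- function(signal_factors) {
    lw <- omics_loading_weights(signal_factors, fs$image)
    load <- matrix(stats::rnorm(length(signal_factors) * d),
                   length(signal_factors), d) * lw
    sig <- if (omics_on) U[, signal_factors, drop = FALSE] %*% load else
      matrix(0, m, d)
    nuis <- matrix(stats::rnorm(m * nuis_rank), m, nuis_rank) %*%
      matrix(stats::rnorm(nuis_rank * d), nuis_rank, d)
    sig + nuis + spec$noise_sd * matrix(stats::rnorm(m * d), m, d)
  }
  expr_raw <- 2^(6 + omics_view(fs$expr))
  expr <- omics_matrix(expr_raw, cell_ids = cell_ids,
                       gene_ids = sprintf("gene_e%04d", seq_len(d)),
                       state = "raw")

  cnv_vals <- 2 + 0.3 * omics_view(fs$cnv)
  cnv <- omics_matrix(cnv_vals, cell_ids = cell_ids,
                      gene_ids = sprintf("gene_c%04d", seq_len(d)),
                      state = "raw")  # CNV is z-scored but never log-scaled

  images <- synth_images(U, fs$image, image_on, spec$image_size, cell_ids)
  drug_ids <- names(graphs)

  # leading (morphology-visible) factors dominate the response, mirroring
  # phenotype-level drivers of drug sensitivity
  w <- rep(1, k)
  w[fs$image] <- 1.5
  score <- (U * rep(w, each = m)) %*% t(V)
  z <- (score - mean(score)) / stats::sd(score)
  eta0 <- spec$logit_scale * z
  intercept <- calibrate_intercept(eta0, spec$sensitive_fraction)
  prob <- sigmoid(eta0 + intercept)
  y <- matrix(stats::rbinom(length(prob), 1, prob), m, spec$n_drugs)

  thresholds <- 10^stats::runif(spec$n_drugs, -0.5, 2)
  off <- matrix(2^stats::runif(m * spec$n_drugs, 0.2, 6), m, spec$n_drugs)
  ic50 <- t(t(ifelse(y == 1, 1 / off, off)) * thresholds)
  measured <- matrix(stats::runif(m * spec$n_drugs) < spec$density,
                     m, spec$n_drugs)
  # every cell line and drug keeps at least one measured pair
  for (i in which(rowSums(measured) == 0)) {
    measured[i, sample.int(spec$n_drugs, 1)] <- TRUE
  }
  for (j in which(colSums(measured) == 0)) {
    measured[sample.int(m, 1), j] <- TRUE
  }
  sel <- which(as.vector(measured))
  response <- response_table(
    cell_line = rep(cell_ids, times = spec$n_drugs)[sel],
    drug = rep(drug_ids, each = m)[sel],
    ic50 = as.vector(ic50)[sel],
    max_screening_conc = rep(thresholds, each = m)[sel])

  cdr_dataset(expr, cnv, images, graphs, response,
              latents = list(U = U, V = V, score = score, prob = prob,
                             spec = spec))
}

# procedural morphology textures: channel means + gratings encode the
# leading latent factors; pixel noise sd 0.02
synth_images <- function(U, factors, image_on, size, cell_ids) {
  m <- nrow(U)
  xg <- matrix(seq_len(size), size, size)
  yg <- t(xg)
  lapply(seq_len(m), function(i) {
    code <- if (image_on) U[i, factors] else stats::rnorm(length(factors))
    code <- rep_len(code, 3)
    means <- 0.5 + 0.28 * tanh(code / 2)
    freq <- 4 + 2 * tanh(code[1])
    phase <- pi * tanh(code[2])
    grating <- 0.0 * sin(2 * pi * freq * (xg + yg) / (2 * size) + phase)
    px <- array(0, dim = c(size, size, 3))
    for (ch in 1:3) {
      px[, , ch] <- means[ch] + grating +
        0.02 * matrix(stats::rnorm(size * size), size, size)
    }
    px[px < 0] <- 0
    px[px > 1] <- 1
    structure(list(pixels = px, cell_id = cell_ids[i]),
              class = "morphology_image")
  })
}

# Drug latents as a deterministic function of molecular structure: a fixed
# random "teacher" graph encoder (same family as the learned one) maps each
# molecule to a code, projected to k dimensions and standardized across the
# library. Structurally similar drugs therefore act similarly - the QSAR
# assumption - and the planted response is recoverable from the graphs.
teacher_drug_latents <- function(graphs, k) {
  pre <- drug_precompute(graphs)
  width <- 16L
  params <- list(G1 = matrix(stats::rnorm(75 * width, sd = 0.3), 75, width),
                 G2 = matrix(stats::rnorm(width * width, sd = 0.3), width,
                             width))
  codes <- drug_forward(pre, params)$Z_drug
  proj <- matrix(stats::rnorm(width * k), width, k)
  V <- codes %*% proj
  V <- sweep(V, 2, colMeans(V))
  n <- nrow(V)
  if (n > k) {
    # orthogonalize so the k planted factors are not confounded with each
    # other across the drug library; still a deterministic graph function
    V <- qr.Q(qr(V)) * sqrt(n - 1)
  } else {
    sdv <- apply(V, 2, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    V <- sweep(V, 2, sdv, "/")
  }
  V
}

calibrate_intercept <- function(eta0, target) {
  fr <- function(c0) mean(sigmoid(eta0 + c0)) - target
  lo <- -60
  hi <- 60
  if (fr(lo) > 0 || fr(hi) < 0) {
    cdr_runtime_error("cannot calibrate sensitive_fraction ", target)
  }
  stats::uniroot(fr, c(lo, hi), tol = 1e-10)$root
}

#' Featurized graphs from the packaged SMILES library
#'
#' @param n Number of drugs (at most the library size).
#' @return Named list of `molecular_graph`s.
#' @export
packaged_drug_graphs <- function(n) {
  path <- system.file("extdata", "smiles_library.csv", package = "mmcdr",
                      mustWork = TRUE)
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (n > nrow(lib)) {
    cdr_validation_error("requested ", n, " drugs but the packaged library ",
                         "has ", nrow(lib))
  }
  graphs <- suppressMessages(lapply(seq_len(n), function(r) {
    featurize_smiles(lib$smiles[r], drug_id = lib$drug_id[r])
  }))
  names(graphs) <- lib$drug_id[seq_len(n)]
  graphs
}

#' Hand-sized worked example
#'
#' A micro dataset (4 cell lines, 3 drugs, 6 genes, 32 px images) together
#' with the intermediate quantities of one deterministic forward pass under
#' fixed seed-42 weights: the standardized omics matrices, the normalized
#' adjacency of each drug, and the attention weights.
#'
#' @param reference_file Optional path; when given, the intermediates are
#'   printed there as plain text for inspection.
#' @return List with `dataset`, `encoded`, `config`, `standardized_expr`,
#'   `standardized_cnv`, `adjacency` (per drug), `attention` (alpha
#'   weights), `probabilities`.
#' @export
make_worked_example <- function(reference_file = NULL) {
  spec <- synthetic_spec(m = 4, n_drugs = 3, d_genes = 6, k = 2,
                         noise_sd = 0.5, seed = 42, image_size = 32)
  dataset <- generate_dataset(spec)
  config <- model_config(f = 3, epochs = 1, folds = 2, seed = 42,
                         image_size = 32)
  enc <- encode_dataset(dataset, config)
  params <- init_params(config, ncol(enc$Xe), ncol(enc$Xc), enc$shapes)
  flags <- model_flags(config)
  fwd <- model_forward(params, enc, config, flags,
                       seq_len(nrow(enc$pairs)), with_cache = TRUE)
  out <- list(
    dataset = dataset, encoded = enc, config = config,
    standardized_expr = enc$Xe, standardized_cnv = enc$Xc,
    adjacency = lapply(enc$drug_pre, function(d) d$A_hat),
    attention = cbind(alpha_g = fwd$cache$fused$alpha_g,
                      alpha_c = fwd$cache$fused$alpha_c),
    probabilities = fwd$p)
  if (!is.null(reference_file)) {
    sink(reference_file)
    on.exit(sink())
    cat("Worked example (seed 42): 4 cell lines x 3 drugs\n\n")
    cat("Standardized expression:\n")
    print(round(out$standardized_expr, 4))
    cat("\nStandardized CNV:\n")
    print(round(out$standardized_cnv, 4))
    cat("\nNormalized adjacencies:\n")
    for (nm in names(out$adjacency)) {
      cat(nm, ":\n")
      print(round(out$adjacency[[nm]], 4))
    }
    cat("\nAttention weights (seed-42 init):\n")
    print(round(out$attention, 4))
    cat("\nPair probabilities (seed-42 init):\n")
    print(round(out$probabilities, 4))
  }
  out
}

#' Write a dataset to disk in the GDSC-style layout
#'
#' Produces `expression.csv`, `cnv.csv`, `drugs.csv`, `response.csv` and
#' one PNG per cell line under `images/` - the exact layout the readers
#' ([read_omics_matrix()], [load_drug_library()], [read_response_table()],
#' [load_image_dir()]) consume.
#'
#' @param dataset A [cdr_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  write_om <- function(om, file) {
    df <- data.frame(cell_line = om$cell_ids, om$values, check.names = FALSE)
    utils::write.csv(df, file.path(dir, file), row.names = FALSE)
  }
  write_om(dataset$expr, "expression.csv")
  write_om(dataset$cnv, "cnv.csv")
  utils::write.csv(data.frame(
    drug_id = names(dataset$graphs),
    smiles = vapply(dataset$graphs, function(g) g$smiles, "")),
    file.path(dir, "drugs.csv"), row.names = FALSE)
  utils::write.csv(dataset$response$records[
    , c("cell_line", "drug", "ic50", "max_screening_conc")],
    file.path(dir, "response.csv"), row.names = FALSE)
  for (im in dataset$images) {
    EBImage::writeImage(EBImage::Image(im$pixels, colormode = "Color"),
                        file.path(dir, "images", paste0(im$cell_id, ".png")))
  }
  invisible(dir)
}

#' Load a dataset from the GDSC-style directory layout
#'
#' Counterpart of [write_dataset()].
#'
#' @param dir Directory with `expression.csv`, `cnv.csv`, `drugs.csv`,
#'   `response.csv` and `images/`.
#' @param image_size Target image size (see [preprocess_image()]).
#' @param ic50_scale Passed to [read_response_table()].
#' @return A [cdr_dataset()].
#' @export
load_dataset <- function(dir, image_size = 224L, ic50_scale = "raw") {
  expr <- read_omics_matrix(file.path(dir, "expression.csv"), state = "raw")
  cnv <- read_omics_matrix(file.path(dir, "cnv.csv"), state = "raw")
  graphs <- load_drug_library(file.path(dir, "drugs.csv"))
  response <- read_response_table(file.path(dir, "response.csv"),
                                  ic50_scale = ic50_scale)
  images <- load_image_dir(file.path(dir, "images"), expr$cell_ids,
                           size = image_size)
  cdr_dataset(expr, cnv, images, graphs, response)
}
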