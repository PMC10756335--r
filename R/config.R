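#' Model configuration
#'
#' Collects every tunable hyperparameter of the multimodal drug-response
#' model. Defaults follow the published training protocol: embedding
#' half-dimension `f = 18` (so cell-line and drug representations are both
#' `2f = 36`-dimensional), contrastive temperature `gamma = 0.01`,
#' loss weights `alpha = 0.6` / `beta = 0.4` (constrained to sum to 1),
#' Adam with learning rate 0.008 and weight decay 1e-5, 2000 epochs and
#' 10-fold cross-validation.
#'
#' @param f Embedding half-dimension; the fused omics and image
#'   representations each have `f` columns and their concatenation `2f`.
#' @param gamma Temperature of the InfoNCE contrastive loss (> 0).
#' @param alpha Weight of the classification cross-entropy term.
#' @param beta Weight of the contrastive term; `alpha + beta` must equal 1.
#' @param lr Adam learning rate.
#' @param weight_decay L2 weight decay added to gradients (Adam style).
#' @param epochs Number of full-batch training epochs.
#' @param folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed controlling parameter init and fold assignment.
#' @param ablation Character vector, subset of
#'   `c("no_image","no_rnaseq","no_cnv","no_attention","no_cl")`.
#' @param normalize_contrastive L2-normalize embeddings before the
#'   contrastive similarity (default `TRUE`; with `gamma = 0.01` raw dot
#'   products would produce unbounded logits).
#' @param ic50_scale Scale on which IC50 is compared with the per-drug
#'   threshold: `"raw"` (micromolar, default) or `"ln"` (both columns
#'   log-transformed before the comparison; the comparison itself is
#'   scale-invariant when both share the scale).
#' @param shared_attention_bias Use a single scalar bias for both attention
#'   score heads instead of one per head (default `FALSE`).
#' @param cnn_channels Integer vector length 2: channels of the two
#'   convolution blocks of the image encoder.
#' @param image_size Spatial input size of the image encoder (pixels).
#'
#' @return An object of class `cdr_config` (a validated list).
#' @export
#' @examples
#' cfg <- model_config(f = 4, epochs = 10, folds = 3, seed = 1)
#' cfg$alpha + cfg$beta
model_config <- function(f = 18L, gamma = 0.01, alpha = 0.6, beta = 0.4,
                         lr = 0.008, weight_decay = 1e-5, epochs = 2000L,
                         folds = 10L, seed = 1L, ablation = character(),
                         normalize_contrastive = TRUE,
                         ic50_scale = c("raw", "ln"),
                         shared_attention_bias = FALSE,
                         cnn_channels = c(8L, 16L),
                         image_size = 224L) {
  ic50_scale <- match.arg(ic50_scale)
  cdr_assert(is.numeric(f) && f >= 1, "f must be >= 1")
  cdr_assert(is.numeric(gamma) && gamma > 0, "gamma (temperature) must be > 0")
  cdr_assert(alpha >= 0 && beta >= 0, "alpha and beta must be non-negative")
  if (abs(alpha + beta - 1) > 1e-8) {
    cdr_validation_error("alpha + beta must equal 1 (got ", alpha, " + ", beta, ")")
  }
  cdr_assert(folds >= 2, "folds must be >= 2")
  cdr_assert(epochs >= 1, "epochs must be >= 1")
  valid_abl <- c("no_image", "no_rnaseq", "no_cnv", "no_attention", "no_cl")
  bad <- setdiff(ablation, valid_abl)
  if (length(bad)) {
    cdr_validation_error("unknown ablation variant(s): ",
                         paste(bad, collapse = ", "),
                         "; valid names: ", paste(valid_abl, collapse = ", "))
  }
  cdr_assert(length(cnn_channels) == 2 && all(cnn_channels >= 1),
             "cnn_channels must be two positive integers")
  structure(list(
    f = as.integer(f), gamma = gamma, alpha = alpha, beta = beta,
    lr = lr, weight_decay = weight_decay, epochs = as.integer(epochs),
    folds = as.integer(folds), seed = as.integer(seed),
    ablation = ablation, normalize_contrastive = normalize_contrastive,
    ic50_scale = ic50_scale, shared_attention_bias = shared_attention_bias,
    cnn_channels = as.integer(cnn_channels), image_size = as.integer(image_size)
  ), class = "cdr_config")
}

# Apply ablation switches that rewrite loss weights.
resolve_config <- function(config) {
  if ("no_cl" %in% config$ablation || "no_image" %in% config$ablation) {
    config$alpha <- 1
    config$beta <- 0
  }
  config
}

#' @export
print.cdr_config <- function(x, ...) {
  cat("Multimodal CDR model configuration\n")
  cat(sprintf("  f = %d (cell/drug representation width 2f = %d)\n", x$f, 2L * x$f))
  cat(sprintf("  gamma = %g, alpha = %g, beta = %g\n", x$gamma, x$alpha, x$beta))
  cat(sprintf("  Adam lr = %g, weight decay = %g, epochs = %d\n",
              x$lr, x$weight_decay, x$epochs))
  cat(sprintf("  folds = %d, seed = %d\n", x$folds, x$seed))
  if (length(x$ablation)) cat("  ablation:", paste(x$ablation, collapse = ", "), "\n")
  invisible(x)
}
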