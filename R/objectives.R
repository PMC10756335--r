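# Training objectives: symmetric omics<->image InfoNCE contrastive loss,
# binary cross-entropy for response classification, and their convex
# combination L = alpha * L_c + beta * L_cl.

#' Symmetric cross-modal contrastive (InfoNCE) loss
#'
#' Rows of the two modality matrices are matched pairs (same cell line).
#' With similarities `s_ij = <h_omics_i, h_image_j>` (on L2-normalized rows
#' by default) and temperature `gamma`, the omics-to-image direction is
#' `L_o2I = -(1/N) sum_i log( exp(s_ii/gamma) / sum_j exp(s_ij/gamma) )`,
#' `L_I2o` is the transposed direction, and `L_cl` is their mean. Matched
#' pairs are pulled together, mismatched pairs within the batch pushed
#' apart.
#'
#' @param h_omics,h_image Matrices N x f, row i of each describing the same
#'   cell line.
#' @param gamma Temperature (> 0).
#' @param normalize L2-normalize rows before the dot products (default
#'   `TRUE`; the small default temperature assumes unit-sphere embeddings).
#' @return List with `L_o2I`, `L_I2o`, `L_cl`.
#' @export
#' @examples
#' h <- diag(2)
#' contrastive_loss(h, h, gamma = 1)$L_cl  # -log(e / (e + 1))
contrastive_loss <- function(h_omics, h_image, gamma, normalize = TRUE) {
  res <- contrastive_loss_grad(h_omics, h_image, gamma, normalize,
                               want_grad = FALSE)
  res[c("L_o2I", "L_I2o", "L_cl")]
}

# Loss plus gradients with respect to both (unnormalized) inputs.
contrastive_loss_grad <- function(h_omics, h_image, gamma, normalize = TRUE,
                                  want_grad = TRUE) {
  if (!is.numeric(gamma) || gamma <= 0) {
    cdr_validation_error("temperature gamma must be > 0")
  }
  h_omics <- as.matrix(h_omics)
  h_image <- as.matrix(h_image)
  N <- nrow(h_omics)
  if (N == 0) cdr_validation_error("contrastive batch is empty")
  cdr_assert(all(dim(h_omics) == dim(h_image)),
             "modality matrices must have identical dimensions")
  Ho <- if (normalize) l2_normalize_rows(h_omics) else h_omics
  Hi <- if (normalize) l2_normalize_rows(h_image) else h_image
  S <- tcrossprod(Ho, Hi) / gamma
  # row-wise and column-wise log-softmax of the diagonal
  rmax <- apply(S, 1, max)
  lse_r <- rmax + log(rowSums(exp(S - rmax)))
  cmax <- apply(S, 2, max)
  lse_c <- cmax + log(rowSums(exp(t(S) - cmax)))
  L_o2I <- mean(lse_r - diag(S))
  L_I2o <- mean(lse_c - diag(S))
  L_cl <- (L_o2I + L_I2o) / 2
  out <- list(L_o2I = L_o2I, L_I2o = L_I2o, L_cl = L_cl)
  if (!want_grad) return(out)
  P <- exp(S - lse_r)            # row softmax
  Q <- exp(t(t(S) - lse_c))      # column softmax
  dS <- (P + Q - 2 * diag(N)) / (2 * N)
  dHo <- dS %*% Hi / gamma
  dHi <- crossprod(dS, Ho) / gamma
  if (normalize) {
    dHo <- normalize_backward(h_omics, Ho, dHo)
    dHi <- normalize_backward(h_image, Hi, dHi)
  }
  c(out, list(dh_omics = dHo, dh_image = dHi))
}

# Backward through row-wise L2 normalization u = v / ||v||.
normalize_backward <- function(v, u, du) {
  nrm <- sqrt(rowSums(v^2))
  nrm[nrm == 0] <- 1
  (du - u * rowSums(u * du)) / nrm
}

#' Binary cross-entropy classification loss
#'
#' `L_c = -sum_i [ y_i log p_i + (1 - y_i) log(1 - p_i) ]`, with
#' probabilities clamped to `[1e-7, 1 - 1e-7]`. The default mean reduction
#' makes the loss-weight combination batch-size independent; `"sum"` gives
#' the literal summed form.
#'
#' @param p Predicted probabilities in (0, 1).
#' @param y Binary labels (0/1).
#' @param reduction `"mean"` (default) or `"sum"`.
#' @return Scalar loss.
#' @export
classification_loss <- function(p, y, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (length(p) != length(y)) {
    cdr_validation_error("length mismatch: ", length(p), " probabilities vs ",
                         length(y), " labels")
  }
  cdr_assert(all(y %in% c(0, 1)), "labels must be 0/1")
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  ll <- -(y * log(p) + (1 - y) * log(1 - p))
  if (reduction == "mean") mean(ll) else sum(ll)
}

#' Combined training loss
#'
#' `L = alpha * L_c + beta * L_cl` with `alpha + beta = 1`; `alpha = 1`
#' disables contrastive learning.
#'
#' @param L_c Classification loss.
#' @param L_cl Contrastive loss.
#' @param alpha,beta Non-negative weights summing to 1.
#' @return Scalar total loss.
#' @export
total_loss <- function(L_c, L_cl, alpha, beta) {
  cdr_assert(alpha >= 0 && beta >= 0, "alpha and beta must be non-negative")
  if (abs(alpha + beta - 1) > 1e-8) {
    cdr_validation_error("alpha + beta must equal 1 (got ", alpha + beta, ")")
  }
  alpha * L_c + beta * L_cl
}
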