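# Cell-line representation: linear omics encoders, softmax attention fusion
# across the two omics views, a two-block CNN image encoder, and the
# concatenation Z_cell = [h_omics, h_image].

#' Linear omics encoder
#'
#' Projects a standardized cell-lines x genes matrix into an f-dimensional
#' embedding by a bias-free linear map `z = M W`. Expression and CNV use
#' separately learned weight matrices.
#'
#' @param M Standardized omics matrix (m x d) or an [omics_matrix()].
#' @param W Weight matrix (d x f).
#' @return Embedding matrix m x f.
#' @export
encode_omics <- function(M, W) {
  v <- if (inherits(M, "omics_matrix")) M$values else as.matrix(M)
  if (ncol(v) != nrow(W)) {
    cdr_validation_error("dimension mismatch: omics matrix is ", nrow(v), "x",
                         ncol(v), " but weights are ", nrow(W), "x", ncol(W))
  }
  cdr_assert(all(is.finite(W)), "weights must be finite")
  v %*% W
}

#' Attention fusion of two omics embeddings
#'
#' Each cell line gets one scalar score per omics view,
#' `w = tanh(z w_score + b)`, and a two-way softmax over the scores yields
#' convex weights `alpha_g + alpha_c = 1`. The fused representation is the
#' per-row convex combination `h_omics = alpha_g * z_g + alpha_c * z_c`.
#'
#' @param z_g,z_c Expression / CNV embeddings (m x f).
#' @param w_g,w_c Score weight vectors (length f).
#' @param b_g,b_c Scalar biases of the two score heads (set `b_c = b_g` to
#'   share a single bias).
#' @return List with `h_omics` (m x f), `alpha_g`, `alpha_c`, and the
#'   pre-softmax scores `w_scores` (m x 2).
#' @export
attention_fuse <- function(z_g, z_c, w_g, w_c, b_g = 0, b_c = 0) {
  cdr_assert(all(dim(z_g) == dim(z_c)),
             "z_g and z_c must have identical dimensions")
  cdr_assert(length(w_g) == ncol(z_g) && length(w_c) == ncol(z_c),
             "score weight length must equal embedding width")
  tg <- tanh(drop(z_g %*% w_g) + b_g)
  tc <- tanh(drop(z_c %*% w_c) + b_c)
  # two-way softmax, numerically stable
  mx <- pmax(tg, tc)
  eg <- exp(tg - mx)
  ec <- exp(tc - mx)
  ag <- eg / (eg + ec)
  ac <- 1 - ag
  h <- z_g * ag + z_c * ac
  list(h_omics = h, alpha_g = ag, alpha_c = ac,
       w_scores = cbind(gene_expression = tg, cnv = tc))
}

# Backward pass of attention_fuse. `cache` is the forward result plus inputs.
attention_backward <- function(dh, z_g, z_c, w_g, w_c, fused) {
  ag <- fused$alpha_g
  ac <- fused$alpha_c
  tg <- fused$w_scores[, 1]
  tc <- fused$w_scores[, 2]
  dag <- rowSums(dh * z_g)
  dac <- rowSums(dh * z_c)
  dtg <- ag * ac * (dag - dac)
  dsg <- dtg * (1 - tg^2)
  dsc <- -dtg * (1 - tc^2)
  list(dz_g = dh * ag + outer(dsg, w_g),
       dz_c = dh * ac + outer(dsc, w_c),
       dw_g = drop(crossprod(z_g, dsg)),
       dw_c = drop(crossprod(z_c, dsc)),
       db_g = sum(dsg), db_c = sum(dsc))
}

#' Concatenate omics and image representations
#'
#' @param h_omics,h_image Matrices m x f.
#' @return `Z_cell`: m x 2f, columns `1..f` are `h_omics`, `f+1..2f` are
#'   `h_image`.
#' @export
build_cell_representation <- function(h_omics, h_image) {
  if (!all(dim(h_omics) == dim(h_image))) {
    cdr_validation_error("h_omics is ", nrow(h_omics), "x", ncol(h_omics),
                         " but h_image is ", nrow(h_image), "x", ncol(h_image))
  }
  cbind(h_omics, h_image)
}

# ---- CNN image encoder ------------------------------------------------------
# conv(3x3, stride 4) -> ReLU -> avgpool(2x2) -> conv(3x3, stride 2) -> ReLU
# -> avgpool(2x2) -> global average pool -> linear to f.
#
# The whole batch is evaluated as a handful of large matrix products:
# im2col patch matrices are stacked across images (the first one is fixed,
# so it is built once per dataset) and pooling / patch extraction reduce to
# precomputed gather indices, keeping every epoch inside BLAS.

cnn_shapes <- function(size, c1, c2, k = 3L, stride1 = 4L, stride2 = 2L) {
  if (size < k + 2 * stride1 * (k - 1)) {
    cdr_validation_error("image size ", size, " too small for the encoder")
  }
  map1 <- im2col_index(size, size, 3L, k, stride1)
  h1 <- map1$ho %/% 2L
  cdr_assert(h1 >= k, "image size ", size, " too small for the encoder")
  map2 <- im2col_index(h1, h1, c1, k, stride2)
  ho2 <- map2$ho
  # trailing 2x2 average pool collapses into the global average pool: GAP
  # over the largest even-sided subgrid (the whole grid when ho2 == 1)
  gap_side <- if (ho2 >= 2) 2L * (ho2 %/% 2L) else ho2
  list(size = size, k = k, stride1 = stride1, stride2 = stride2,
       c1 = c1, c2 = c2, map1 = map1, h1 = h1, map2 = map2,
       npos1 = map1$ho * map1$wo, npos2 = ho2 * map2$wo,
       ho2 = ho2, gap_side = gap_side)
}

cnn_init_params <- function(shapes, f) {
  # small positive conv biases keep ReLU units alive at initialization
  list(K1 = glorot(shapes$k^2 * 3, shapes$c1),
       b1 = rep(0.05, shapes$c1),
       K2 = glorot(shapes$k^2 * shapes$c1, shapes$c2),
       b2 = rep(0.05, shapes$c2),
       # scaled up so h_image starts on the same magnitude as the omics
       # embeddings; GAP features are compressed relative to standardized
       # omics and a balanced start lets the head use both halves equally
       Wp = 4 * glorot(shapes$c2, f),
       bp = numeric(f))
}

# Batch-level constants: the stacked conv1 patch matrix plus gather/scatter
# index tables for pooling, the second im2col and the GAP region.
cnn_precompute <- function(imgarr, shapes) {
  m <- dim(imgarr)[1]
  npos1 <- shapes$npos1
  COL1 <- matrix(0, m * npos1, ncol(shapes$map1$idx))
  for (i in seq_len(m)) {
    COL1[(i - 1) * npos1 + seq_len(npos1), ] <-
      im2col(array(imgarr[i, , , ], dim = dim(imgarr)[-1]), shapes$map1)
  }
  ho1 <- shapes$map1$ho
  h1 <- shapes$h1
  # 2x2 pool taps: position p=(r,c) of the pooled grid reads conv1 rows
  # (2r-1, 2c-1) .. (2r, 2c)
  pr <- rep(seq_len(h1), times = h1)
  pc <- rep(seq_len(h1), each = h1)
  q <- function(dr, dc) (2 * pr - 2 + dr) + (2 * pc - 2 + dc) * ho1 + 1L
  qtaps <- cbind(q(0, 0), q(1, 0), q(0, 1), q(1, 1))
  img_off1 <- rep((seq_len(m) - 1L) * npos1, each = h1 * h1)
  Gq <- lapply(1:4, function(t) img_off1 + rep(qtaps[, t], m))
  # second im2col as linear indices into the pooled (m*h1^2) x c1 matrix
  idx2 <- shapes$map2$idx                    # into an (h1, h1, c1) array
  pos_of <- (idx2 - 1L) %% (h1 * h1) + 1L
  ch_of <- (idx2 - 1L) %/% (h1 * h1)
  lin0 <- ch_of * (m * h1 * h1) + pos_of     # image offset added per block
  npos2 <- shapes$npos2
  IDX2 <- lin0[rep(seq_len(npos2), m), , drop = FALSE] +
    rep((seq_len(m) - 1L) * (h1 * h1), each = npos2)
  storage.mode(IDX2) <- "integer"
  # scatter plan for the conv2 -> pool1 gradient (fixed across epochs)
  iv <- as.vector(IDX2)
  ord <- order(iv)
  sorted <- iv[ord]
  ends <- c(which(diff(sorted) != 0), length(sorted))
  targets <- sorted[ends]
  # GAP region: even-sided subgrid of the conv2 output
  gs <- shapes$gap_side
  sr <- rep(seq_len(gs), times = gs)
  sc <- rep(seq_len(gs), each = gs)
  sub <- (sr - 1L) + (sc - 1L) * shapes$ho2 + 1L
  sub_rows <- rep((seq_len(m) - 1L) * npos2, each = length(sub)) +
    rep(sub, m)
  list(COL1 = COL1, m = m, Gq = Gq, IDX2 = IDX2,
       scatter = list(ord = ord, ends = ends, targets = targets,
                      size = m * h1 * h1 * shapes$c1),
       sub_rows = sub_rows, gap_grp = rep(seq_len(m), each = length(sub)),
       gap_n = length(sub))
}

cnn_forward <- function(pre, params, shapes) {
  m <- pre$m
  Z1 <- relu(sweep(pre$COL1 %*% params$K1, 2, params$b1, "+"))
  P1 <- (Z1[pre$Gq[[1]], , drop = FALSE] + Z1[pre$Gq[[2]], , drop = FALSE] +
           Z1[pre$Gq[[3]], , drop = FALSE] + Z1[pre$Gq[[4]], , drop = FALSE]) / 4
  COL2 <- matrix(P1[pre$IDX2], nrow = nrow(pre$IDX2))
  Z2 <- relu(sweep(COL2 %*% params$K2, 2, params$b2, "+"))
  G <- rowsum(Z2[pre$sub_rows, , drop = FALSE], pre$gap_grp) / pre$gap_n
  dimnames(G) <- NULL
  h <- sweep(G %*% params$Wp, 2, params$bp, "+")
  list(h_image = h,
       cache = list(Z1 = Z1, P1 = P1, COL2 = COL2, Z2 = Z2, G = G))
}

cnn_backward <- function(dh, pre, params, shapes, cache) {
  m <- pre$m
  grads <- list(Wp = crossprod(cache$G, dh), bp = colSums(dh))
  dG <- dh %*% t(params$Wp)
  dZ2 <- matrix(0, nrow(cache$Z2), shapes$c2)
  dZ2[pre$sub_rows, ] <- dG[pre$gap_grp, , drop = FALSE] / pre$gap_n
  dZ2[cache$Z2 <= 0] <- 0
  grads$K2 <- crossprod(cache$COL2, dZ2)
  grads$b2 <- colSums(dZ2)
  dCOL2 <- dZ2 %*% t(params$K2)
  # scatter-add back onto the pooled layer with the precomputed plan
  sc <- pre$scatter
  v <- as.vector(dCOL2)[sc$ord]
  cs <- cumsum(v)[sc$ends]
  dP1vec <- numeric(sc$size)
  dP1vec[sc$targets] <- diff(c(0, cs))
  dP1 <- matrix(dP1vec, ncol = shapes$c1)
  dZ1 <- matrix(0, nrow(cache$Z1), shapes$c1)
  g <- dP1 / 4
  dZ1[pre$Gq[[1]], ] <- g
  dZ1[pre$Gq[[2]], ] <- g
  dZ1[pre$Gq[[3]], ] <- g
  dZ1[pre$Gq[[4]], ] <- g
  dZ1[cache$Z1 <= 0] <- 0
  grads$K1 <- crossprod(pre$COL1, dZ1)
  grads$b1 <- colSums(dZ1)
  grads
}

#' Encode morphology images into f-dimensional representations
#'
#' Runs the two-block convolutional encoder (conv 3x3 stride 2, ReLU, 2x2
#' average pooling, twice), a global average pool, and a linear head. The
#' encoder is deterministic given its weights.
#'
#' @param images List of `morphology_image` objects (see
#'   [preprocess_image()]) or an `m x size x size x 3` array.
#' @param params CNN parameter list from the trained model (or
#'   `cnn_init_params()`).
#' @param config A [model_config()]; `image_size` and `cnn_channels` must
#'   match the images and parameters.
#' @return Matrix m x f.
#' @export
encode_image <- function(images, params, config = model_config()) {
  arr <- if (is.list(images) && !is.array(images)) stack_images(images) else images
  d <- dim(arr)
  if (length(d) != 4 || d[2] != config$image_size || d[3] != config$image_size ||
      d[4] != 3) {
    cdr_validation_error("images must be m x ", config$image_size, " x ",
                         config$image_size, " x 3; got ",
                         paste(d, collapse = " x "))
  }
  shapes <- cnn_shapes(config$image_size, config$cnn_channels[1],
                       config$cnn_channels[2])
  pre <- cnn_precompute(arr, shapes)
  cnn_forward(pre, params, shapes)$h_image
}
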