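# Dataset assembly: validates the five inputs, runs preprocessing, and
# precomputes everything the training loop reuses every epoch (standardized
# omics, stacked image columns, normalized drug adjacencies, pair indices).

#' Bundle the five raw inputs into a dataset
#'
#' @param expr,cnv [omics_matrix()] objects (cell lines x genes), rows in
#'   the same cell-line order.
#' @param images List of `morphology_image` objects, one per cell line, in
#'   the same order.
#' @param graphs Named list of `molecular_graph` objects.
#' @param response A `cdr_response_table`; every cell line / drug it
#'   references must be present.
#' @param latents Optional list of generator ground truth (synthetic data).
#' @return A `cdr_dataset`.
#' @export
cdr_dataset <- function(expr, cnv, images, graphs, response, latents = NULL) {
  cell_ids <- expr$cell_ids
  cdr_assert(identical(cell_ids, cnv$cell_ids),
             "expression and CNV matrices list different cell lines")
  img_ids <- vapply(images, function(im) im$cell_id %||% NA_character_, "")
  cdr_assert(identical(as.character(img_ids), as.character(cell_ids)),
             "image cell ids do not match omics cell ids")
  drug_ids <- names(graphs)
  missing_cells <- setdiff(response$cell_ids, cell_ids)
  if (length(missing_cells)) {
    cdr_validation_error("response table references unknown cell line(s): ",
                         paste(utils::head(missing_cells, 5), collapse = ", "))
  }
  missing_drugs <- setdiff(response$drug_ids, drug_ids)
  if (length(missing_drugs)) {
    cdr_validation_error("response table references unknown drug(s): ",
                         paste(utils::head(missing_drugs, 5), collapse = ", "))
  }
  structure(list(expr = expr, cnv = cnv, images = images, graphs = graphs,
                 response = response, cell_ids = cell_ids,
                 drug_ids = drug_ids, latents = latents),
            class = "cdr_dataset")
}

#' @export
print.cdr_dataset <- function(x, ...) {
  cat(sprintf(paste0("Multimodal CDR dataset: %d cell lines, %d genes (expr), ",
                     "%d genes (CNV), %d drugs, %d labeled pairs\n"),
              length(x$cell_ids), length(x$expr$gene_ids),
              length(x$cnv$gene_ids), length(x$drug_ids),
              nrow(x$response$records)))
  invisible(x)
}

#' Preprocess and encode a dataset for training
#'
#' Expression is zero-filled, log-TPM transformed (if raw) and z-scored per
#' gene; CNV is zero-filled and z-scored; images are stacked and their
#' first-convolution patch matrix precomputed; drug graphs get their
#' normalized adjacencies. The result is what [train_model()] and
#' [cross_validate()] consume.
#'
#' @param dataset A [cdr_dataset()].
#' @param config A [model_config()].
#' @return A `cdr_encoded_dataset` list.
#' @export
encode_dataset <- function(dataset, config = model_config()) {
  cdr_assert(inherits(dataset, "cdr_dataset"), "dataset must be a cdr_dataset")
  expr <- dataset$expr
  if (expr$state == "raw") expr <- log_tpm_transform(fill_missing(expr))
  if (expr$state != "standardized") expr <- gaussian_normalize(fill_missing(expr))
  cnv <- dataset$cnv
  if (cnv$state != "standardized") cnv <- gaussian_normalize(fill_missing(cnv))

  imgarr <- stack_images(dataset$images)
  cdr_assert(dim(imgarr)[2] == config$image_size,
             "images are ", dim(imgarr)[2], " px but config$image_size is ",
             config$image_size)
  shapes <- cnn_shapes(config$image_size, config$cnn_channels[1],
                       config$cnn_channels[2])
  rec <- dataset$response$records
  pairs <- data.frame(
    cell = match(rec$cell_line, dataset$cell_ids),
    drug = match(rec$drug, dataset$drug_ids),
    label = rec$label)
  structure(list(
    Xe = expr$values, Xc = cnv$values,
    img_pre = cnn_precompute(imgarr, shapes), shapes = shapes,
    drug_pre = drug_precompute(dataset$graphs),
    pairs = pairs, cell_ids = dataset$cell_ids, drug_ids = dataset$drug_ids,
    records = rec, m = length(dataset$cell_ids),
    n_drugs = length(dataset$drug_ids)
  ), class = "cdr_encoded_dataset")
}

#' Score a cell line-drug pair with the MLP prediction head
#'
#' Concatenates the 2f-dimensional cell-line and drug representations and
#' applies the head `4f -> 2f -> 1` (ReLU hidden layer, sigmoid output).
#'
#' @param z_cell,z_drug Numeric vectors of length 2f (or matrices with
#'   matching row counts).
#' @param head_params List with `H1` (4f x 2f), `h1b`, `H2` (2f x 1), `h2b`.
#' @return Probability (or vector of probabilities) in (0, 1).
#' @export
predict_pair <- function(z_cell, z_drug, head_params) {
  zc <- if (is.matrix(z_cell)) z_cell else matrix(z_cell, nrow = 1)
  zd <- if (is.matrix(z_drug)) z_drug else matrix(z_drug, nrow = 1)
  cdr_assert(nrow(zc) == nrow(zd), "row count mismatch between cell and drug")
  Zp <- cbind(zc, zd)
  if (ncol(Zp) != nrow(head_params$H1)) {
    cdr_validation_error("pair vector has length ", ncol(Zp),
                         " but head expects ", nrow(head_params$H1))
  }
  A1 <- relu(sweep(Zp %*% head_params$H1, 2, head_params$h1b, "+"))
  drop(sigmoid(A1 %*% head_params$H2 + head_params$h2b))
}

# ---- full-model forward / backward -----------------------------------------

model_flags <- function(config) {
  abl <- config$ablation
  use_expr <- !("no_rnaseq" %in% abl)
  use_cnv <- !("no_cnv" %in% abl)
  use_image <- !("no_image" %in% abl)
  list(use_expr = use_expr, use_cnv = use_cnv, use_image = use_image,
       use_attention = use_expr && use_cnv && !("no_attention" %in% abl),
       use_cl = use_image && (use_expr || use_cnv) &&
         !("no_cl" %in% abl) && config$beta > 0)
}

init_params <- function(config, d_e, d_c, shapes) {
  f <- config$f
  set.seed(config$seed)
  c(list(We = glorot(d_e, f), Wc = glorot(d_c, f),
         att_wg = stats::runif(f, -0.1, 0.1),
         att_wc = stats::runif(f, -0.1, 0.1),
         att_bg = 0, att_bc = 0),
    cnn_init_params(shapes, f),
    list(G1 = glorot(75, 2 * f), G2 = glorot(2 * f, 2 * f),
         H1 = glorot(4 * f, 2 * f), h1b = numeric(2 * f),
         H2 = glorot(2 * f, 1), h2b = 0))
}

active_param_names <- function(flags) {
  nm <- c("H1", "h1b", "H2", "h2b", "G1", "G2")
  if (flags$use_expr) nm <- c(nm, "We")
  if (flags$use_cnv) nm <- c(nm, "Wc")
  if (flags$use_attention) nm <- c(nm, "att_wg", "att_wc", "att_bg", "att_bc")
  if (flags$use_image) nm <- c(nm, "K1", "b1", "K2", "b2", "Wp", "bp")
  nm
}

model_forward <- function(params, enc, config, flags, pair_rows,
                          with_cache = FALSE) {
  f <- config$f
  m <- enc$m
  z_g <- if (flags$use_expr) enc$Xe %*% params$We else NULL
  z_c <- if (flags$use_cnv) enc$Xc %*% params$Wc else NULL
  fused <- NULL
  if (flags$use_expr && flags$use_cnv) {
    if (flags$use_attention) {
      b_c <- if (config$shared_attention_bias) params$att_bg else params$att_bc
      fused <- attention_fuse(z_g, z_c, params$att_wg, params$att_wc,
                              params$att_bg, b_c)
      h_omics <- fused$h_omics
    } else {
      h_omics <- (z_g + z_c) / 2
    }
  } else if (flags$use_expr) {
    h_omics <- z_g
  } else if (flags$use_cnv) {
    h_omics <- z_c
  } else {
    h_omics <- matrix(0, m, f)
  }
  cnn <- NULL
  if (flags$use_image) {
    cnn <- cnn_forward(enc$img_pre, params, enc$shapes)
    h_image <- cnn$h_image
  } else {
    h_image <- matrix(0, m, f)
  }
  Z_cell <- build_cell_representation(h_omics, h_image)
  dr <- drug_forward(enc$drug_pre, params)
  pr <- enc$pairs[pair_rows, , drop = FALSE]
  Zp <- cbind(Z_cell[pr$cell, , drop = FALSE], dr$Z_drug[pr$drug, , drop = FALSE])
  A1pre <- sweep(Zp %*% params$H1, 2, params$h1b, "+")
  A1 <- relu(A1pre)
  logits <- drop(A1 %*% params$H2) + params$h2b
  p <- sigmoid(logits)
  L_c <- classification_loss(p, pr$label)
  cl <- if (flags$use_cl) {
    contrastive_loss_grad(h_omics, h_image, config$gamma,
                          config$normalize_contrastive, want_grad = with_cache)
  } else list(L_cl = 0)
  L <- total_loss(L_c, cl$L_cl, config$alpha, config$beta)
  out <- list(L = L, L_c = L_c, L_cl = cl$L_cl, p = p,
              Z_cell = Z_cell, Z_drug = dr$Z_drug)
  if (with_cache) {
    out$cache <- list(z_g = z_g, z_c = z_c, fused = fused, h_omics = h_omics,
                      h_image = h_image, cnn = cnn, dr = dr, pr = pr, Zp = Zp,
                      A1pre = A1pre, A1 = A1, cl = cl)
  }
  out
}

model_backward <- function(params, enc, config, flags, fwd) {
  f <- config$f
  m <- enc$m
  ca <- fwd$cache
  S <- nrow(ca$pr)
  grads <- list()
  # classification head
  dlogit <- config$alpha * (fwd$p - ca$pr$label) / S
  grads$H2 <- crossprod(ca$A1, dlogit)
  grads$h2b <- sum(dlogit)
  dA1 <- outer(dlogit, drop(params$H2))
  dA1[ca$A1pre <= 0] <- 0
  grads$H1 <- crossprod(ca$Zp, dA1)
  grads$h1b <- colSums(dA1)
  dZp <- dA1 %*% t(params$H1)
  dZ_cell <- accumulate_rows(dZp[, 1:(2 * f), drop = FALSE], ca$pr$cell, m)
  dZ_drug <- accumulate_rows(dZp[, (2 * f + 1):(4 * f), drop = FALSE],
                             ca$pr$drug, enc$n_drugs)
  dh_omics <- dZ_cell[, 1:f, drop = FALSE]
  dh_image <- dZ_cell[, (f + 1):(2 * f), drop = FALSE]
  if (flags$use_cl) {
    dh_omics <- dh_omics + config$beta * ca$cl$dh_omics
    dh_image <- dh_image + config$beta * ca$cl$dh_image
  }
  # omics branch
  if (flags$use_expr && flags$use_cnv) {
    if (flags$use_attention) {
      ab <- attention_backward(dh_omics, ca$z_g, ca$z_c,
                               params$att_wg, params$att_wc, ca$fused)
      dz_g <- ab$dz_g
      dz_c <- ab$dz_c
      grads$att_wg <- ab$dw_g
      grads$att_wc <- ab$dw_c
      if (config$shared_attention_bias) {
        grads$att_bg <- ab$db_g + ab$db_c
        grads$att_bc <- 0
      } else {
        grads$att_bg <- ab$db_g
        grads$att_bc <- ab$db_c
      }
    } else {
      dz_g <- dh_omics / 2
      dz_c <- dh_omics / 2
    }
  } else {
    dz_g <- if (flags$use_expr) dh_omics else NULL
    dz_c <- if (flags$use_cnv) dh_omics else NULL
  }
  if (flags$use_expr) grads$We <- crossprod(enc$Xe, dz_g)
  if (flags$use_cnv) grads$Wc <- crossprod(enc$Xc, dz_c)
  if (flags$use_image) {
    grads <- c(grads, cnn_backward(dh_image, enc$img_pre, params, enc$shapes,
                                   ca$cnn$cache))
  }
  grads <- c(grads, drug_backward(dZ_drug, enc$drug_pre, params, ca$dr$cache))
  grads
}
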