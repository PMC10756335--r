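# Training loop (full-batch Adam on the combined loss), stratified k-fold
# cross-validation over labeled pairs, ranking metrics, and the ablation
# grid.

#' Train the multimodal drug-response model
#'
#' Full-batch optimization: every epoch encodes all cell lines and drugs,
#' scores all training pairs, and takes one Adam step on
#' `L = alpha * L_c + beta * L_cl`. The contrastive batch is the full set
#' of cell lines (the split is over pairs, so features stay transductive
#' while labels remain inductive). Deterministic given `config$seed`.
#'
#' @param enc A `cdr_encoded_dataset` (see [encode_dataset()]) or a
#'   [cdr_dataset()], which is encoded first.
#' @param config A [model_config()].
#' @param pair_rows Integer rows of `enc$pairs` to train on (default: all).
#' @return A `cdr_model`: list with `params`, `config`, `flags`, and
#'   `log` (per-epoch data.frame of `L`, `L_c`, `L_cl`).
#' @export
train_model <- function(enc, config = model_config(), pair_rows = NULL) {
  if (inherits(enc, "cdr_dataset")) enc <- encode_dataset(enc, config)
  config <- resolve_config(config)
  flags <- model_flags(config)
  if (is.null(pair_rows)) pair_rows <- seq_len(nrow(enc$pairs))
  cdr_assert(length(pair_rows) >= 1, "no training pairs")
  params <- init_params(config, ncol(enc$Xe), ncol(enc$Xc), enc$shapes)
  active <- active_param_names(flags)
  state <- adam_init(params[active])
  log_df <- data.frame(epoch = seq_len(config$epochs), L = NA_real_,
                       L_c = NA_real_, L_cl = NA_real_)
  for (ep in seq_len(config$epochs)) {
    fwd <- model_forward(params, enc, config, flags, pair_rows,
                         with_cache = TRUE)
    if (!is.finite(fwd$L)) {
      cdr_runtime_error("non-finite loss at epoch ", ep, " (L_c = ", fwd$L_c,
                        ", L_cl = ", fwd$L_cl, ")")
    }
    log_df$L[ep] <- fwd$L
    log_df$L_c[ep] <- fwd$L_c
    log_df$L_cl[ep] <- fwd$L_cl
    grads <- model_backward(params, enc, config, flags, fwd)
    upd <- adam_step(params[active], grads[active], state,
                     lr = config$lr, weight_decay = config$weight_decay)
    params[active] <- upd$params
    state <- upd$state
  }
  structure(list(params = params, config = config, flags = flags,
                 log = log_df), class = "cdr_model")
}

#' Predict response probabilities for pairs
#'
#' @param object A trained `cdr_model`.
#' @param enc The encoded dataset the model was trained on (features are
#'   transductive; test-fold cell lines are encoded the same way).
#' @param pair_rows Rows of `enc$pairs` to score (default: all).
#' @param ... Unused.
#' @return Numeric vector of sensitivity probabilities.
#' @export
predict.cdr_model <- function(object, enc, pair_rows = NULL, ...) {
  if (is.null(pair_rows)) pair_rows <- seq_len(nrow(enc$pairs))
  fwd <- model_forward(object$params, enc, object$config, object$flags,
                       pair_rows, with_cache = FALSE)
  fwd$p
}

#' Export cell-line and drug embeddings
#'
#' @param model A trained `cdr_model`.
#' @param enc The encoded dataset.
#' @return List with `cell` (m x 2f, rownames = cell ids) and `drug`
#'   (n_drugs x 2f, rownames = drug ids).
#' @export
export_embeddings <- function(model, enc) {
  fwd <- model_forward(model$params, enc, model$config, model$flags,
                       pair_rows = 1L, with_cache = FALSE)
  cell <- fwd$Z_cell
  drug <- fwd$Z_drug
  rownames(cell) <- enc$cell_ids
  rownames(drug) <- enc$drug_ids
  list(cell = cell, drug = drug)
}

#' Ranking metrics: AUROC and AUPR
#'
#' AUROC uses the Mann-Whitney rank statistic with midrank tie correction;
#' AUPR integrates the precision-recall curve over distinct score
#' thresholds (step integration).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels; both classes must be present.
#' @return Named list with `auc` and `aupr`.
#' @export
#' @examples
#' compute_metrics(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$auc  # 0.75
compute_metrics <- function(scores, labels) {
  cdr_assert(length(scores) == length(labels), "scores/labels length mismatch")
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    cdr_validation_error("both classes must be present to compute AUC/AUPR")
  }
  r <- rank(scores)   # midranks handle ties
  auc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  grp_end <- c(which(diff(s) != 0), length(s))   # last index of each tie group
  tp <- cumsum(y)[grp_end]
  n_at <- grp_end
  precision <- tp / n_at
  recall <- tp / npos
  aupr <- sum(diff(c(0, recall)) * precision)
  list(auc = auc, aupr = aupr)
}

#' Stratified fold assignment over labeled pairs
#'
#' Pairs are shuffled within each label class and dealt round-robin so that
#' fold sizes differ by at most one and each fold keeps both classes.
#'
#' @param labels Binary label vector.
#' @param k Number of folds.
#' @param seed RNG seed (same seed, same folds).
#' @return Integer fold id per pair (1..k).
#' @export
make_folds <- function(labels, k, seed) {
  cdr_assert(length(labels) >= k, "need at least as many pairs as folds")
  set.seed(seed)
  fold <- integer(length(labels))
  counter <- 0L
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((counter + seq_along(idx) - 1L) %% k) + 1L
    counter <- counter + length(idx)
  }
  fold
}

#' k-fold cross-validation of the multimodal model
#'
#' Pairs are partitioned into `config$folds` stratified folds; each fold is
#' held out once while the model trains on the rest. Per-fold and mean
#' AUROC/AUPR are reported together with per-pair predictions.
#'
#' @param dataset A [cdr_dataset()] or `cdr_encoded_dataset`.
#' @param config A [model_config()].
#' @param folds Optional precomputed fold vector (to share folds across
#'   ablation variants).
#' @return A `cdr_eval_report`: list with `per_fold` (data.frame),
#'   `mean_auc`, `mean_aupr`, `predictions` (data.frame), `config`.
#' @export
cross_validate <- function(dataset, config = model_config(), folds = NULL) {
  enc <- if (inherits(dataset, "cdr_dataset")) {
    encode_dataset(dataset, config)
  } else dataset
  n_pairs <- nrow(enc$pairs)
  cdr_assert(n_pairs >= config$folds, "fewer labeled pairs than folds")
  if (is.null(folds)) folds <- make_folds(enc$pairs$label, config$folds,
                                          config$seed)
  per_fold <- data.frame(fold = seq_len(config$folds), auc = NA_real_,
                         aupr = NA_real_, n_test = NA_integer_)
  preds <- vector("list", config$folds)
  for (kf in seq_len(config$folds)) {
    test_rows <- which(folds == kf)
    train_rows <- which(folds != kf)
    if (length(unique(enc$pairs$label[test_rows])) < 2) {
      cdr_runtime_error("fold ", kf, " contains a single class; AUC is ",
                        "undefined - use stratified folds or another seed")
    }
    cfg_fold <- config
    cfg_fold$seed <- config$seed + kf
    model <- train_model(enc, cfg_fold, pair_rows = train_rows)
    p <- predict(model, enc, pair_rows = test_rows)
    met <- compute_metrics(p, enc$pairs$label[test_rows])
    per_fold$auc[kf] <- met$auc
    per_fold$aupr[kf] <- met$aupr
    per_fold$n_test[kf] <- length(test_rows)
    preds[[kf]] <- data.frame(
      cell_line = enc$cell_ids[enc$pairs$cell[test_rows]],
      drug = enc$drug_ids[enc$pairs$drug[test_rows]],
      score = p, label = enc$pairs$label[test_rows], fold = kf,
      stringsAsFactors = FALSE)
  }
  structure(list(per_fold = per_fold,
                 mean_auc = mean(per_fold$auc),
                 mean_aupr = mean(per_fold$aupr),
                 predictions = do.call(rbind, preds),
                 folds = folds, config = config),
            class = "cdr_eval_report")
}

#' @export
print.cdr_eval_report <- function(x, ...) {
  cat(sprintf("Cross-validated evaluation (%d folds)\n", nrow(x$per_fold)))
  cat(sprintf("  mean AUROC = %.4f, mean AUPR = %.4f\n",
              x$mean_auc, x$mean_aupr))
  if (length(x$config$ablation)) {
    cat("  ablation:", paste(x$config$ablation, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run the ablation grid
#'
#' Evaluates the full model and the requested ablation variants with
#' identical folds and seeds, so differences reflect the removed component
#' only. Variants: `no_image` (drop the image branch; the cell
#' representation is `h_omics` zero-padded to 2f and the contrastive term
#' is skipped), `no_rnaseq` / `no_cnv` (single-omics passthrough, attention
#' bypassed), `no_attention` (unweighted mean fusion), `no_cl`
#' (`alpha = 1, beta = 0`).
#'
#' @param dataset A [cdr_dataset()] or `cdr_encoded_dataset`.
#' @param config A [model_config()]; its `ablation` field is ignored.
#' @param variants Character vector of variant names (see above);
#'   `"full"` is always included first. A variant may combine switches as
#'   `"no_rnaseq+no_cnv"`.
#' @return A `cdr_ablation_table`: named list of `cdr_eval_report`s plus a
#'   `summary` data.frame.
#' @export
run_ablation <- function(dataset, config = model_config(),
                         variants = c("no_image", "no_rnaseq", "no_cnv",
                                      "no_attention", "no_cl")) {
  enc <- if (inherits(dataset, "cdr_dataset")) {
    encode_dataset(dataset, config)
  } else dataset
  folds <- make_folds(enc$pairs$label, config$folds, config$seed)
  variants <- unique(c("full", variants))
  reports <- vector("list", length(variants))
  names(reports) <- variants
  for (v in variants) {
    cfg <- config
    cfg$ablation <- if (v == "full") character() else
      strsplit(v, "+", fixed = TRUE)[[1]]
    bad <- setdiff(cfg$ablation,
                   c("no_image", "no_rnaseq", "no_cnv", "no_attention", "no_cl"))
    if (length(bad)) {
      cdr_validation_error("unknown ablation variant '", v, "'; valid: ",
                           "no_image, no_rnaseq, no_cnv, no_attention, no_cl")
    }
    reports[[v]] <- cross_validate(enc, cfg, folds = folds)
  }
  summary <- data.frame(
    variant = variants,
    mean_auc = vapply(reports, function(r) r$mean_auc, 0),
    mean_aupr = vapply(reports, function(r) r$mean_aupr, 0),
    row.names = NULL)
  structure(list(reports = reports, summary = summary),
            class = "cdr_ablation_table")
}

#' @export
print.cdr_ablation_table <- function(x, ...) {
  cat("Ablation grid (shared folds and seeds)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Save / load a trained model
#'
#' The checkpoint is a single RDS archive of the named parameter tensors,
#' the configuration, and a hash of the configuration for integrity checks.
#'
#' @param model A `cdr_model`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  cdr_assert(inherits(model, "cdr_model"), "not a cdr_model")
  payload <- list(version = 1L, params = model$params, config = model$config,
                  flags = model$flags,
                  config_hash = config_hash(model$config))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$config_hash, config_hash(payload$config))) {
    cdr_runtime_error("checkpoint ", path, " failed its configuration hash check")
  }
  structure(list(params = payload$params, config = payload$config,
                 flags = payload$flags, log = NULL), class = "cdr_model")
}

config_hash <- function(config) {
  digest_input <- paste(utils::capture.output(utils::str(unclass(config))),
                        collapse = "\n")
  # content hash without external digest packages
  sum(utf8ToInt(digest_input) * seq_len(nchar(digest_input))) %% 2147483647
}
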