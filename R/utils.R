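#' @keywords internal
"_PACKAGE"

# Internal error helpers: validation errors abort with a classed condition so
# the CLI can map them to exit code 2 (validation) vs 3 (runtime/numerical).
cdr_validation_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("cdr_validation_error", "error")))
}

cdr_runtime_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("cdr_runtime_error", "error")))
}

cdr_assert <- function(cond, ...) {
  if (!isTRUE(cond)) cdr_validation_error(...)
  invisible(TRUE)
}

# Accumulate rows of `d` into an n-row matrix by integer index (used to
# collect per-pair gradients back onto shared cell-line / drug embeddings).
accumulate_rows <- function(d, idx, n) {
  out <- matrix(0, n, ncol(d))
  agg <- rowsum(d, group = idx)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Row-wise L2 normalization with a zero-row guard.
l2_normalize_rows <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  x / nrm
}
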