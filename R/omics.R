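#' Construct an omics matrix
#'
#' A cell-lines x genes real matrix (gene expression or copy-number
#' variation) that tracks its normalization state through the preprocessing
#' pipeline: `raw` -> (`log_tpm`) -> `standardized`.
#'
#' @param values Numeric matrix, cell lines in rows, genes in columns.
#' @param cell_ids,gene_ids Row/column identifiers (default: dimnames).
#' @param state Normalization state: `"raw"`, `"log_tpm"` or `"standardized"`.
#' @return An `omics_matrix` object.
#' @export
omics_matrix <- function(values, cell_ids = rownames(values),
                         gene_ids = colnames(values),
                         state = c("raw", "log_tpm", "standardized")) {
  state <- match.arg(state)
  values <- as.matrix(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(values)))
  cdr_assert(length(cell_ids) == nrow(values), "cell_ids length != nrow(values)")
  cdr_assert(length(gene_ids) == ncol(values), "gene_ids length != ncol(values)")
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 state = state), class = "omics_matrix")
}

#' Read an omics matrix from CSV/TSV
#'
#' First column holds cell-line identifiers, the header row gene
#' identifiers. The delimiter is inferred from the extension (`.tsv`/`.txt`
#' use tab, otherwise comma).
#'
#' @param path File path.
#' @param state Declared normalization state of the stored values.
#' @return An [omics_matrix()].
#' @export
read_omics_matrix <- function(path, state = "raw") {
  if (!file.exists(path)) cdr_validation_error("omics matrix not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  omics_matrix(as.matrix(df), state = state)
}

#' Zero-fill missing omics entries
#'
#' Missing values in both the gene-expression and copy-number matrices are
#' replaced by zeros; observed entries are untouched.
#'
#' @param mat An [omics_matrix()] (or plain matrix).
#' @return Same type as the input with `NA`/`NaN` replaced by 0.
#' @export
fill_missing <- function(mat) {
  if (inherits(mat, "omics_matrix")) {
    mat$values[is.na(mat$values)] <- 0
    return(mat)
  }
  mat[is.na(mat)] <- 0
  mat
}

#' Log-transform TPM-scale expression values
#'
#' Elementwise `log2(x + 1)` on non-negative TPM-scale values. The base-2
#' log with unit pseudocount is the dominant convention for log-TPM.
#'
#' @param mat An [omics_matrix()] in `raw` state (or plain matrix).
#' @return The transformed matrix; state advances to `log_tpm`.
#' @export
log_tpm_transform <- function(mat) {
  v <- if (inherits(mat, "omics_matrix")) mat$values else mat
  if (any(v < 0, na.rm = TRUE)) {
    cdr_validation_error("log-TPM transform requires non-negative values; ",
                         "first offender at index ",
                         which(v < 0)[1])
  }
  out <- log2(v + 1)
  if (inherits(mat, "omics_matrix")) {
    mat$values <- out
    mat$state <- "log_tpm"
    return(mat)
  }
  out
}

#' Gaussian (z-score) normalization per gene
#'
#' Each gene column is centered by its mean and scaled by its population
#' standard deviation (divisor m, not m-1). Zero-variance columns are mapped
#' to all-zero rather than dividing by zero.
#'
#' @param mat An [omics_matrix()] or plain matrix without missing values
#'   (apply [fill_missing()] first).
#' @return Standardized matrix; state advances to `standardized`.
#' @export
#' @examples
#' gaussian_normalize(matrix(c(1, 2, 3), ncol = 1))
gaussian_normalize <- function(mat) {
  v <- if (inherits(mat, "omics_matrix")) mat$values else mat
  if (anyNA(v)) cdr_validation_error("missing values present; call fill_missing() first")
  m <- nrow(v)
  mu <- colMeans(v)
  centered <- sweep(v, 2, mu)
  sigma <- sqrt(colSums(centered^2) / m)  # population sd
  keep <- sigma > 0
  centered[, keep] <- sweep(centered[, keep, drop = FALSE], 2, sigma[keep], "/")
  centered[, !keep] <- 0
  if (inherits(mat, "omics_matrix")) {
    mat$values <- centered
    mat$state <- "standardized"
    return(mat)
  }
  centered
}
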