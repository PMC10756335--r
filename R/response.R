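#' Binarize a drug-response measurement
#'
#' A cell line is called *sensitive* (label 1) to a drug when its IC50 does
#' not exceed the drug's maximum screening concentration, and *resistant*
#' (label 0) otherwise. The comparison is inclusive: an IC50 exactly at the
#' threshold is sensitive.
#'
#' @param ic50 IC50 value(s), micromolar, finite and >= 0. Vectorized.
#' @param threshold Per-drug maximum screening concentration(s), > 0, on the
#'   same scale as `ic50`.
#' @param record Optional record identifier(s) used in error messages.
#' @return Integer vector of 0/1 labels (1 = sensitive).
#' @export
#' @examples
#' binarize_response(566.28, 32)  # resistant
#' binarize_response(32, 32)      # boundary is sensitive
binarize_response <- function(ic50, threshold, record = NULL) {
  bad <- !is.finite(ic50) | ic50 < 0
  if (any(bad)) {
    id <- if (!is.null(record)) paste(record[bad], collapse = ", ") else
      paste("index", paste(which(bad), collapse = ", "))
    cdr_validation_error("non-finite or negative IC50 in record(s): ", id)
  }
  if (any(!is.finite(threshold) | threshold <= 0)) {
    cdr_validation_error("thresholds must be finite and > 0")
  }
  as.integer(ic50 <= threshold)
}

#' Read a drug-response table
#'
#' Expects a CSV with columns `cell_line`, `drug`, `ic50`,
#' `max_screening_conc` (micromolar). Each (cell line, drug) pair may appear
#' at most once. The binarized label matrix `A` has one row per cell line
#' and one column per drug; entries without a measured record are `NA` and
#' are excluded from training and evaluation.
#'
#' @param path CSV file path.
#' @param ic50_scale `"raw"` compares micromolar values directly; `"ln"`
#'   log-transforms both IC50 and threshold before the (scale-invariant)
#'   comparison.
#' @return A `cdr_response_table`: list with `records` (data.frame),
#'   `label_matrix` (cell lines x drugs, 0/1/NA), `cell_ids`, `drug_ids`.
#' @export
read_response_table <- function(path, ic50_scale = c("raw", "ln")) {
  ic50_scale <- match.arg(ic50_scale)
  if (!file.exists(path)) cdr_validation_error("response table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "drug", "ic50", "max_screening_conc")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    cdr_validation_error("response table ", path, " lacks column(s): ",
                         paste(missing_cols, collapse = ", "))
  }
  response_table(df$cell_line, df$drug, df$ic50, df$max_screening_conc,
                 ic50_scale = ic50_scale)
}

#' Build a response table from vectors
#'
#' @param cell_line,drug Character identifiers.
#' @param ic50,max_screening_conc Numeric, micromolar.
#' @inheritParams read_response_table
#' @return A `cdr_response_table` (see [read_response_table()]).
#' @export
response_table <- function(cell_line, drug, ic50, max_screening_conc,
                           ic50_scale = c("raw", "ln")) {
  ic50_scale <- match.arg(ic50_scale)
  key <- paste(cell_line, drug, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    cdr_validation_error("duplicate (cell line, drug) record: ",
                         gsub("\r", " / ", d, fixed = TRUE))
  }
  ic50_cmp <- ic50
  thr_cmp <- max_screening_conc
  if (ic50_scale == "ln") {
    # log of a positive pair preserves the ordering; zeros stay sensitive
    ic50_cmp <- log(pmax(ic50, .Machine$double.xmin))
    thr_cmp <- log(thr_cmp)
    # binarize_response requires ic50 >= 0; shift both sides equally
    shift <- min(ic50_cmp, thr_cmp)
    ic50_cmp <- ic50_cmp - shift
    thr_cmp <- thr_cmp - shift + .Machine$double.eps
  }
  labels <- binarize_response(ic50_cmp, thr_cmp,
                              record = paste(cell_line, drug, sep = "/"))
  records <- data.frame(cell_line = as.character(cell_line),
                        drug = as.character(drug),
                        ic50 = ic50, max_screening_conc = max_screening_conc,
                        label = labels, stringsAsFactors = FALSE)
  cell_ids <- unique(records$cell_line)
  drug_ids <- unique(records$drug)
  A <- matrix(NA_integer_, length(cell_ids), length(drug_ids),
              dimnames = list(cell_ids, drug_ids))
  A[cbind(match(records$cell_line, cell_ids), match(records$drug, drug_ids))] <-
    records$label
  structure(list(records = records, label_matrix = A,
                 cell_ids = cell_ids, drug_ids = drug_ids),
            class = "cdr_response_table")
}

#' @export
print.cdr_response_table <- function(x, ...) {
  cat(sprintf("Drug-response table: %d records, %d cell lines x %d drugs\n",
              nrow(x$records), length(x$cell_ids), length(x$drug_ids)))
  cat(sprintf("  sensitive: %d, resistant: %d\n",
              sum(x$records$label == 1), sum(x$records$label == 0)))
  invisible(x)
}
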