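#' Signature-based cell-type abundance scores
#'
#' Scores each cell type in each sample as the arithmetic mean of the
#' normalized expression of its signature genes — a relative abundance
#' proxy, not an absolute composition estimate. Signature genes absent
#' from the expression matrix are dropped with a message; a cell type with
#' no present genes is dropped with a warning.
#'
#' @param expr normalized expression matrix (genes x samples). The
#'   pipeline's TMM-scaled log2-TPM by default; pass a linear-scale matrix
#'   for linear averaging.
#' @param signatures named list of signature gene vectors per cell type.
#' @return numeric matrix (cell type x sample) with attribute
#'   `scale = "raw_mean"`.
#' @export
estimate_abundance <- function(expr, signatures) {
  if (length(signatures) == 0) {
    out <- matrix(numeric(0), 0, ncol(expr),
                  dimnames = list(NULL, colnames(expr)))
    attr(out, "scale") <- "raw_mean"
    return(out)
  }
  rows <- lapply(names(signatures), function(ct) {
    present <- intersect(unique(signatures[[ct]]), rownames(expr))
    lost <- setdiff(unique(signatures[[ct]]), present)
    if (length(lost)) {
      message("cell type '", ct, "': ", length(lost),
              " signature gene(s) not measured")
    }
    if (length(present) == 0) {
      warning("cell type '", ct, "' has no measured signature genes; dropped")
      return(NULL)
    }
    colMeans(expr[present, , drop = FALSE])
  })
  names(rows) <- names(signatures)
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) stop("no cell type has measured signature genes")
  out <- do.call(rbind, rows)
  attr(out, "scale") <- "raw_mean"
  out
}

#' Standardize abundance scores across samples
#'
#' Z-scores each cell-type row across samples (sample standard deviation)
#' for cross-type display; constant rows become zero and are flagged.
#' Idempotent up to floating tolerance.
#'
#' @param table an [estimate_abundance()] matrix with >= 2 samples.
#' @return matrix with attribute `scale = "zscore_by_type"` and
#'   `constant_types` naming flagged rows.
#' @export
zscore_abundance <- function(table) {
  if (ncol(table) < 2) stop("need at least 2 samples")
  z <- zscore_rows(table)
  const <- attr(z, "constant_rows")
  attr(z, "constant_rows") <- NULL
  attr(z, "scale") <- "zscore_by_type"
  attr(z, "constant_types") <- rownames(table)[const]
  z
}
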