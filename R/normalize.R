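#' Transcripts-per-million from counts and effective lengths
#'
#' `tpm(g, s) = (count(g,s) / length(g)) / sum_g'(count(g',s) / length(g'))
#' * 1e6`. Columns of all-zero counts yield all-zero TPM.
#'
#' @param counts non-negative matrix (genes x samples).
#' @param gene_lengths named positive vector of effective lengths (nt)
#'   covering all genes.
#' @return TPM matrix of the same shape.
#' @export
compute_tpm <- function(counts, gene_lengths) {
  if (is.null(gene_lengths)) stop("gene lengths are required for TPM")
  lens <- gene_lengths[rownames(counts)]
  if (any(is.na(lens))) stop("missing gene lengths")
  rate <- counts / lens
  denom <- colSums(rate)
  denom[denom == 0] <- 1  # all-zero sample stays all-zero
  sweep(rate, 2, denom, "/") * 1e6
}

## Upper-quartile of count proportions, edgeR-style, used to pick the TMM
## reference sample.
upper_quartile_prop <- function(counts) {
  lib <- colSums(counts)
  apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
}

## Single TMM factor of `obs` against `ref` (count vectors): 30%/5% double
## trim by ranks of M and A, inverse-binomial-variance weighting.
tmm_pair_factor <- function(obs, ref, logratio_trim = 0.3, sum_trim = 0.05) {
  n_obs <- sum(obs)
  n_ref <- sum(ref)
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(NA_real_)
  obs <- obs[keep]
  ref <- ref[keep]
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  rL <- rank(logR)
  rS <- rank(absE)
  keep2 <- rL >= loL & rL <= hiL & rS >= loS & rS <= hiS
  f <- sum(logR[keep2] / v[keep2], na.rm = TRUE) /
    sum(1 / v[keep2], na.rm = TRUE)
  if (!is.finite(f)) return(1)
  2^f
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes one between-sample scaling factor per library by the standard
#' TMM procedure: the reference is the sample whose upper-quartile count
#' proportion is closest to the mean upper quartile; for each sample,
#' genes expressed in both the sample and the reference contribute an
#' M-value (log2 ratio of proportions) and an A-value (average log2
#' proportion); M is trimmed 30% two-sided and A 5% two-sided by ranks, and
#' the factor is 2 to the precision-weighted mean of the retained M-values.
#' Factors are rescaled to geometric mean 1.
#'
#' @param counts non-negative count matrix with >= 2 samples, each with
#'   positive total counts.
#' @param reference optional sample identifier forcing the reference.
#' @param logratio_trim,sum_trim two-sided trim fractions for M and A.
#' @return list of class `"tmm_factors"` with `factors` (named positive
#'   vector, geometric mean 1) and `reference`.
#' @export
tmm_factors <- function(counts, reference = NULL,
                        logratio_trim = 0.3, sum_trim = 0.05) {
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  if (is.null(reference)) {
    f75 <- upper_quartile_prop(counts)
    reference <- colnames(counts)[which.min(abs(f75 - mean(f75)))]
  } else if (!reference %in% colnames(counts)) {
    stop("reference sample not found: ", reference)
  }
  ref_col <- counts[, reference]
  f <- vapply(colnames(counts), function(s) {
    fs <- tmm_pair_factor(counts[, s], ref_col, logratio_trim, sum_trim)
    if (is.na(fs)) {
      warning("sample '", s, "' shares no expressed genes with the ",
              "reference; factor set to 1")
      fs <- 1
    }
    fs
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(list(factors = f, reference = reference), class = "tmm_factors")
}

#' TMM-normalized log2-TPM expression matrix
#'
#' Applies the TMM factor to each sample's library size inside the TPM
#' denominator (so a factor above 1 shrinks that sample's normalized
#' values), then takes `log2(TPM + pseudocount)`. The normalization
#' provenance (factors, reference, pseudocount, unit) is attached as the
#' `"normalization"` attribute.
#'
#' @param counts count matrix (genes x samples).
#' @param gene_lengths named effective-length vector.
#' @param factors a [tmm_factors()] result (or NULL for factors of 1).
#' @param pseudocount positive offset added before log2.
#' @return numeric matrix of log2 expression values.
#' @export
normalize_expression <- function(counts, gene_lengths, factors = NULL,
                                 pseudocount = 1) {
  stopifnot_scalar_number(pseudocount, "pseudocount", positive = TRUE)
  if (is.null(factors)) {
    f <- stats::setNames(rep(1, ncol(counts)), colnames(counts))
    ref <- NA_character_
  } else {
    f <- factors$factors
    ref <- factors$reference
    missing <- setdiff(colnames(counts), names(f))
    if (length(missing)) {
      stop("no TMM factor for sample(s): ", paste(missing, collapse = ", "))
    }
    f <- f[colnames(counts)]
  }
  tpm <- compute_tpm(counts, gene_lengths)
  tpm <- sweep(tpm, 2, f, "/")
  expr <- log2(tpm + pseudocount)
  attr(expr, "normalization") <- list(
    method = "TMM-scaled log2-TPM", factors = f, reference = ref,
    pseudocount = pseudocount, unit = "log2(TPM + pseudocount)"
  )
  expr
}

#' Sample-level PCA of an expression matrix
#'
#' PCA of samples on gene-centered (not gene-scaled) expression values,
#' reporting per-sample coordinates and the percentage of variance
#' explained by each axis.
#'
#' @param expr numeric matrix (genes x samples), >= 2 samples.
#' @return list with `coordinates` (samples x PCs) and
#'   `var_explained_pct` (non-increasing percentages summing to <= 100).
#' @export
qc_pca <- function(expr) {
  if (ncol(expr) < 2) stop("PCA needs at least 2 samples")
  centred <- expr - rowMeans(expr)
  pc <- stats::prcomp(t(centred), center = FALSE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  if (tot < 1e-24) {
    warning("samples are identical; variance fractions undefined, reported 0")
    frac <- rep(0, length(pc$sdev))
  } else {
    frac <- pc$sdev^2 / tot
  }
  list(coordinates = pc$x, var_explained_pct = 100 * frac)
}

#' Gene-wise z-scored matrix with hierarchical clustering orders
#'
#' Standardizes each gene across samples (sample sd; constant genes become
#' all-zero and are flagged) and clusters rows and columns with Euclidean
#' distance and average linkage, returning the leaf orders used for heatmap
#' display.
#'
#' @param expr numeric matrix (genes x samples), >= 2 samples.
#' @return list with `z` (z-score matrix), `row_order`, `col_order` (leaf
#'   index orders) and `constant_genes` (identifiers of zero-variance rows).
#' @export
qc_heatmap_matrix <- function(expr) {
  if (ncol(expr) < 2) stop("need at least 2 samples")
  z <- zscore_rows(expr)
  constant <- attr(z, "constant_rows")
  row_order <- if (nrow(z) > 1) {
    stats::hclust(stats::dist(z), method = "average")$order
  } else 1L
  col_order <- if (ncol(z) > 1) {
    stats::hclust(stats::dist(t(z)), method = "average")$order
  } else 1L
  list(z = z, row_order = row_order, col_order = col_order,
       constant_genes = rownames(expr)[constant])
}
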