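#' Read a gene-level count matrix from TSV
#'
#' The file must have a header row of sample identifiers and gene
#' identifiers in the first column. Entries must be non-negative integers.
#' `#`-prefixed comment lines are ignored.
#'
#' @param counts_path path to the counts TSV.
#' @param lengths_path optional path to a two-column TSV (gene, effective
#'   length in nt). When supplied, every gene in the count matrix must have
#'   a positive length.
#' @return list with `counts` (integer matrix) and `gene_lengths` (named
#'   numeric vector or NULL).
#' @export
read_counts <- function(counts_path, lengths_path = NULL) {
  df <- utils::read.delim(counts_path, header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("counts TSV needs a gene column plus >= 1 sample")
  genes <- as.character(df[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stop("duplicated gene identifiers: ", paste(dup, collapse = ", "))
  }
  samp <- colnames(df)[-1]
  dup_s <- unique(samp[duplicated(samp)])
  if (length(dup_s)) {
    stop("duplicated sample identifiers: ", paste(dup_s, collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-integer or negative count at gene '%s', sample '%s' (value %s)",
      genes[bad[1, 1]], samp[bad[1, 2]], format(m[bad[1, , drop = FALSE]])
    ))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  lengths <- NULL
  if (!is.null(lengths_path)) {
    lt <- utils::read.delim(lengths_path, header = TRUE, comment.char = "#",
                            stringsAsFactors = FALSE)
    lengths <- stats::setNames(as.numeric(lt[[2]]), as.character(lt[[1]]))
    missing <- setdiff(genes, names(lengths))
    if (length(missing)) {
      stop("genes without effective length: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    lengths <- lengths[genes]
    if (any(!is.finite(lengths) | lengths <= 0)) {
      stop("all gene lengths must be positive")
    }
  }
  list(counts = m, gene_lengths = lengths)
}

#' Write a count matrix as TSV
#'
#' Inverse of [read_counts()]: `write_counts()` followed by `read_counts()`
#' round-trips exactly for integer matrices.
#'
#' @param counts integer matrix (genes x samples).
#' @param path output TSV path.
#' @param gene_column name of the first column.
#' @export
write_counts <- function(counts, path, gene_column = "gene") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- gene_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects columns `sample`, `tissue`, `timepoint_dpa`, `treatment`,
#' `replicate`. Validates uniqueness of the design tuples and (optionally)
#' agreement with a count matrix.
#'
#' @param path TSV path.
#' @param counts optional count matrix whose columns the table must cover
#'   exactly.
#' @return data.frame of sample metadata.
#' @export
read_sample_table <- function(path, counts = NULL) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  needed <- c("sample", "tissue", "timepoint_dpa", "treatment", "replicate")
  missing <- setdiff(needed, colnames(df))
  if (length(missing)) {
    stop("sample table lacks columns: ", paste(missing, collapse = ", "))
  }
  key <- do.call(paste, df[c("tissue", "timepoint_dpa", "treatment", "replicate")])
  if (anyDuplicated(key)) {
    stop("duplicate (tissue, timepoint, treatment, replicate) tuples")
  }
  if (anyDuplicated(df$sample)) stop("duplicate sample identifiers")
  if (!is.null(counts)) {
    if (!setequal(colnames(counts), df$sample)) {
      stop("sample table and count matrix describe different samples")
    }
  }
  df
}

#' Read a GMT gene-set file
#'
#' Standard tab-delimited GMT: set name, description, then member genes.
#' Duplicate genes within a set are removed.
#'
#' @param path GMT path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) stop("GMT lines need name, description and >= 1 gene")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read cell-type signatures from GMT or two-column TSV
#'
#' A file ending in `.gmt` is parsed as GMT; otherwise it is read as a
#' two-column TSV (`cell_type`, `gene`) and split by cell type.
#'
#' @param path input path.
#' @return named list of gene vectors per cell type.
#' @export
read_signatures <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    return(read_gmt(path))
  }
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("signature TSV needs columns cell_type and gene")
  split(as.character(df[[2]]), as.character(df[[1]]))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
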