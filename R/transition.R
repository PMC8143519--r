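#' Control-to-treatment cluster-transition matrix
#'
#' Cross-tabulates, for every gene with both a control-arm and a
#' treatment-arm assignment in a joint clustering fit, the control cluster
#' (rows) against the treatment cluster (columns). Proportions are
#' row-normalized, so row `i` gives the distribution of genes from control
#' cluster `i` over treatment clusters; off-diagonal mass indicates genes
#' whose temporal program was re-timed by the treatment. Genes present in
#' only one arm are excluded and reported.
#'
#' @param model a [fuzzy_cmeans()] model fitted on merged
#'   [build_profiles()] rows (it must carry the row `meta`).
#' @param treatments the (control, treatment) pair of labels.
#' @return list of class `"transition_matrix"` with `counts` (c x c
#'   integer), `proportions` (row-stochastic; empty rows all zero and
#'   listed in `empty_rows`) and `n_genes`.
#' @export
compute_transition_matrix <- function(model,
                                      treatments = c("control", "inhibitor")) {
  amap <- assignment_by_treatment(model, treatments)
  cc <- model$c
  counts <- matrix(0L, cc, cc,
                   dimnames = list(paste0("C", seq_len(cc)),
                                   paste0("C", seq_len(cc))))
  tab <- table(factor(amap$from, levels = seq_len(cc)),
               factor(amap$to, levels = seq_len(cc)))
  counts[] <- as.integer(tab)
  rs <- rowSums(counts)
  proportions <- counts / ifelse(rs == 0, 1, rs)
  empty <- which(rs == 0)
  structure(list(counts = counts, proportions = proportions,
                 empty_rows = unname(empty), n_genes = nrow(amap)),
            class = "transition_matrix")
}

## Pair each gene's control and treatment assignments; genes with a single
## arm are dropped with a message.
assignment_by_treatment <- function(model, treatments) {
  if (is.null(model$meta)) {
    stop("model carries no row metadata; fit fuzzy_cmeans on build_profiles output")
  }
  meta <- model$meta
  a <- model$assignment
  ctrl <- meta$treatment == treatments[1]
  trt <- meta$treatment == treatments[2]
  from <- stats::setNames(a[ctrl], meta$gene[ctrl])
  to <- stats::setNames(a[trt], meta$gene[trt])
  common <- intersect(names(from), names(to))
  lone <- setdiff(union(names(from), names(to)), common)
  if (length(lone)) {
    message(length(lone), " gene(s) with a single treatment arm excluded")
  }
  data.frame(gene = common, from = unname(from[common]),
             to = unname(to[common]), stringsAsFactors = FALSE)
}

#' Genes following a specific cluster transition
#'
#' @param model a joint [fuzzy_cmeans()] model with row metadata.
#' @param from_cluster control-arm cluster index.
#' @param to_cluster treatment-arm cluster index (`from == to` means "no
#'   transition").
#' @param treatments the (control, treatment) label pair.
#' @return sorted character vector of gene identifiers.
#' @export
extract_transition_genes <- function(model, from_cluster, to_cluster,
                                     treatments = c("control", "inhibitor")) {
  cc <- model$c
  if (from_cluster < 1 || from_cluster > cc || to_cluster < 1 ||
      to_cluster > cc) {
    stop(sprintf("cluster indices must lie in [1, %d]", cc))
  }
  amap <- assignment_by_treatment(model, treatments)
  sort(amap$gene[amap$from == from_cluster & amap$to == to_cluster])
}
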