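#' Read a pipeline configuration file
#'
#' YAML with either an `input:` block (paths to counts, lengths, samples,
#' optional gene_sets GMT and signatures) or a `simulate:` block
#' (arguments of [simulation_config()]), a `seed`, optional `tissue`
#' selection, and a `params:` block of stage parameters (pseudocount,
#' p_cut, fuzzifier, clusters, scan_range, theta, n_perm, q_cut, sim_cut,
#' restarts, top_transitions).
#'
#' @param path YAML file path.
#' @return configuration list for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

pipeline_defaults <- function() {
  list(pseudocount = 1, p_cut = 0.05, fuzzifier = NULL, clusters = NULL,
       scan_range = c(4, 27), theta = 0.3, n_perm = 1000L, q_cut = 0.05,
       sim_cut = 0.25, restarts = 3L, top_transitions = 3L)
}

#' Run the full cluster-transition pipeline
#'
#' Executes, per tissue arm: TMM normalization to log2-TPM, moderated-t
#' differential expression over the six stage comparisons, the
#' dynamic-gene filter, merged control/treatment temporal profiles, fuzzy
#' c-means (with cluster-number scan unless overridden), the
#' cluster-transition matrix, per-transition gene lists with ORA,
#' stage-wise preranked GSEA, and signature-based cell abundance. Every
#' intermediate table is written as TSV under `out_dir` and indexed in a
#' JSON manifest with md5 checksums, so identical (config, seed) runs are
#' bit-reproducible.
#'
#' @param config configuration list (see [read_pipeline_config()]).
#' @param out_dir output directory (created if needed); defaults to
#'   `config$out_dir`.
#' @return the manifest list, invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir) {
  if (is.null(out_dir)) stop("an output directory is required")
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim) {
    stop("config must contain exactly one of 'input' or 'simulate'")
  }
  seed <- as.integer(config$seed %||% 1L)
  params <- utils::modifyList(pipeline_defaults(), config$params %||% list())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  add_output <- function(path) outputs <<- c(outputs, path)

  if (has_sim) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% seed
    if (!is.null(sim_args$timepoints)) {
      sim_args$timepoints <- as.numeric(sim_args$timepoints)
    }
    sim_cfg <- do.call(simulation_config, sim_args)
    sim <- simulate_counts(sim_cfg)
    gs <- generate_gene_sets(sim$ground_truth, sim_cfg)
    gene_sets <- gs$sets
    signatures <- sim$ground_truth$signatures
    counts <- sim$counts
    samples <- sim$samples
    lengths <- sim$gene_lengths
    in_dir <- file.path(out_dir, "input")
    dir.create(in_dir, showWarnings = FALSE)
    add_output(write_counts(counts, file.path(in_dir, "counts.tsv")))
    add_output(write_tsv(samples, file.path(in_dir, "samples.tsv")))
    add_output(write_tsv(
      data.frame(gene = names(lengths), length = unname(lengths)),
      file.path(in_dir, "gene_lengths.tsv")
    ))
    add_output(write_gmt(gene_sets, file.path(in_dir, "gene_sets.gmt")))
    if (length(signatures)) {
      add_output(write_gmt(signatures, file.path(in_dir, "signatures.gmt")))
    }
  } else {
    inp <- config$input
    cm <- read_counts(inp$counts, inp$lengths)
    counts <- cm$counts
    lengths <- cm$gene_lengths
    samples <- read_sample_table(inp$samples, counts)
    gene_sets <- if (!is.null(inp$gene_sets)) read_gmt(inp$gene_sets) else NULL
    signatures <- if (!is.null(inp$signatures)) {
      read_signatures(inp$signatures)
    } else NULL
  }

  tissues <- config$tissue %||% unique(samples$tissue)
  stages <- list()
  for (tissue in tissues) {
    tdir <- file.path(out_dir, tissue)
    dir.create(tdir, showWarnings = FALSE)
    smp <- samples[samples$tissue == tissue, , drop = FALSE]
    cnt <- counts[, smp$sample, drop = FALSE]

    factors <- tmm_factors(cnt)
    expr <- normalize_expression(cnt, lengths, factors,
                                 pseudocount = params$pseudocount)
    add_output(write_tsv(
      data.frame(sample = names(factors$factors),
                 tmm_factor = unname(factors$factors)),
      file.path(tdir, "tmm_factors.tsv")
    ))

    de <- run_de(expr, smp)
    de_tab <- do.call(rbind, de$results)
    add_output(write_tsv(de_tab, file.path(tdir, "differential_expression.tsv")))

    dynamic <- select_dynamic_genes(de$results, p_cut = params$p_cut)
    add_output(write_tsv(data.frame(gene = dynamic),
                         file.path(tdir, "dynamic_genes.tsv")))

    profiles <- build_profiles(expr, smp, dynamic)
    m <- params$fuzzifier %||% estimate_fuzzifier(profiles)
    if (is.null(params$clusters)) {
      scan <- select_cluster_number(profiles, m,
                                    c_range = params$scan_range,
                                    theta = params$theta, seed = seed,
                                    restarts = params$restarts)
      add_output(write_tsv(scan$scan, file.path(tdir, "cluster_scan.tsv")))
      n_clusters <- scan$chosen
    } else {
      n_clusters <- params$clusters
    }
    model <- fuzzy_cmeans(profiles, c = n_clusters, m = m, seed = seed,
                          restarts = params$restarts)
    assign_tab <- data.frame(
      gene = model$meta$gene, treatment = model$meta$treatment,
      cluster = unname(model$assignment),
      max_membership = apply(model$membership, 1, max)
    )
    add_output(write_tsv(assign_tab, file.path(tdir, "cluster_assignments.tsv")))
    add_output(write_tsv(
      data.frame(cluster = rownames(model$centroids), model$centroids),
      file.path(tdir, "cluster_centroids.tsv")
    ))

    tm <- compute_transition_matrix(model)
    add_output(write_tsv(
      data.frame(from = rownames(tm$counts), tm$counts),
      file.path(tdir, "transition_counts.tsv")
    ))
    add_output(write_tsv(
      data.frame(from = rownames(tm$proportions), tm$proportions),
      file.path(tdir, "transition_proportions.tsv")
    ))

    ## strongest off-diagonal transitions: gene lists + ORA
    off <- tm$counts
    diag(off) <- 0L
    ord <- order(off, decreasing = TRUE)
    ord <- ord[off[ord] > 0]
    ord <- utils::head(ord, params$top_transitions)
    universe <- rownames(expr)
    transition_stats <- list()
    for (cell in ord) {
      i <- (cell - 1) %% nrow(off) + 1
      j <- (cell - 1) %/% nrow(off) + 1
      genes_ij <- extract_transition_genes(model, i, j)
      tag <- sprintf("C%d_to_C%d", i, j)
      add_output(writeLines_path(genes_ij,
                                 file.path(tdir, paste0("transition_", tag,
                                                        "_genes.txt"))))
      if (!is.null(gene_sets)) {
        ora <- ora_hypergeometric(genes_ij, gene_sets, universe)
        add_output(write_tsv(ora, file.path(tdir, paste0("ora_", tag, ".tsv"))))
        transition_stats[[tag]] <- nrow(ora)
      }
    }

    if (!is.null(gene_sets)) {
      gsea_contrasts <- intersect(c("3v0_ctrl", "8v0_ctrl", "3v0_inh",
                                    "8v0_inh"), names(de$results))
      nes_rows <- list()
      for (k in seq_along(gsea_contrasts)) {
        nm <- gsea_contrasts[k]
        ranked <- rank_genes(de$results[[nm]])
        g <- gsea_preranked(ranked, gene_sets, n_perm = params$n_perm,
                            seed = seed + 100L * k)
        g$contrast <- nm
        nes_rows[[nm]] <- g
      }
      gsea_tab <- do.call(rbind, nes_rows)
      rownames(gsea_tab) <- NULL
      add_output(write_tsv(gsea_tab[, c("contrast", "set", "size", "es",
                                        "nes", "p", "q")],
                           file.path(tdir, "gsea_stagewise.tsv")))
    }

    if (!is.null(signatures) && length(signatures)) {
      ab <- estimate_abundance(expr, signatures)
      abz <- zscore_abundance(ab)
      add_output(write_tsv(
        data.frame(cell_type = rownames(ab), ab, check.names = FALSE),
        file.path(tdir, "abundance_raw.tsv")
      ))
      add_output(write_tsv(
        data.frame(cell_type = rownames(abz), abz, check.names = FALSE),
        file.path(tdir, "abundance_zscore.tsv")
      ))
    }

    stages[[tissue]] <- list(
      n_samples = nrow(smp), n_genes = nrow(cnt),
      n_dynamic = length(dynamic), fuzzifier = m, clusters = n_clusters,
      n_transition_genes = tm$n_genes
    )
  }

  manifest <- list(
    package = "clustershift",
    version = as.character(utils::packageVersion("clustershift")),
    seed = seed, params = params, tissues = tissues, stages = stages,
    outputs = lapply(
      stats::setNames(outputs,
                      substring(outputs, nchar(out_dir) + 2L)),
      function(p) list(md5 = unname(tools::md5sum(p)))
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

writeLines_path <- function(lines, path) {
  writeLines(lines, path)
  invisible(path)
}
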