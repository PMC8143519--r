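#' Simulation configuration for the synthetic time-course generator
#'
#' Bundles and validates all parameters of the synthetic bulk RNA-seq
#' generator. The defaults emulate a two-tissue regeneration time course:
#' 3 timepoints (0, 3, 8 days post-amputation), a shared homeostatic 0-dpa
#' baseline, control and inhibitor arms from 3 dpa on, and two replicates
#' per condition.
#'
#' @param n_genes number of genes to simulate.
#' @param n_archetypes number of distinct temporal archetype shapes.
#' @param timepoints ordered numeric timepoint labels (dpa). The first
#'   timepoint is the homeostatic baseline shared by both treatments.
#' @param treatments two treatment labels; the first is the control arm.
#' @param n_replicates replicates per (tissue, timepoint, treatment) group.
#' @param tissues tissue labels; each tissue is an independent arm with the
#'   same planted structure.
#' @param frac_shifted fraction of genes given a premature temporal shift
#'   under the inhibitor.
#' @param shift_from index of the control archetype from which shifted genes
#'   are drawn (default 1, the monotone-up trend).
#' @param baseline_mean expected count scale of an unperturbed gene.
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2). `0` requests the deterministic noise-free
#'   limit in which counts equal rounded expected means.
#' @param amplitude log2-scale amplitude multiplying archetype values.
#' @param library_size_factors optional per-sample positive multipliers of
#'   expected counts; recycled per tissue arm. Default all 1.
#' @param noise_sd standard deviation of log2-scale biological noise added
#'   per gene and sample.
#' @param n_gene_sets number of gene sets emitted by
#'   [generate_gene_sets()] (one planted, the rest decoys).
#' @param set_size_range integer pair of minimum/maximum set sizes.
#' @param n_cell_types number of synthetic cell types with planted
#'   signatures.
#' @param signature_size signature genes per cell type.
#' @param seed integer seed making every generated artifact reproducible.
#'
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_archetypes = 8,
                              timepoints = c(0, 3, 8),
                              treatments = c("control", "inhibitor"),
                              n_replicates = 2,
                              tissues = c("epidermis", "soft_tissue"),
                              frac_shifted = 0.1,
                              shift_from = 1,
                              baseline_mean = 100,
                              dispersion = 0.05,
                              amplitude = 2,
                              library_size_factors = NULL,
                              noise_sd = 0.25,
                              n_gene_sets = 20,
                              set_size_range = c(20, 60),
                              n_cell_types = 3,
                              signature_size = 20,
                              seed = 1L) {
  stopifnot_scalar_number(n_genes, "n_genes", positive = TRUE)
  stopifnot_scalar_number(n_archetypes, "n_archetypes", positive = TRUE)
  stopifnot_scalar_number(baseline_mean, "baseline_mean", positive = TRUE)
  stopifnot_scalar_number(dispersion, "dispersion", nonnegative = TRUE)
  stopifnot_scalar_number(amplitude, "amplitude")
  stopifnot_scalar_number(noise_sd, "noise_sd", nonnegative = TRUE)
  stopifnot_scalar_number(frac_shifted, "frac_shifted", nonnegative = TRUE)
  if (frac_shifted > 1) stop("'frac_shifted' must lie in [0, 1]")
  if (n_replicates != round(n_replicates) || n_replicates < 1) {
    stop("'n_replicates' must be a positive integer")
  }
  if (length(timepoints) < 3) {
    stop("'timepoints' must contain at least 3 ordered timepoints")
  }
  if (is.unsorted(timepoints, strictly = TRUE)) {
    stop("'timepoints' must be strictly increasing")
  }
  if (length(treatments) != 2) stop("exactly two treatments are supported")
  if (length(set_size_range) != 2 || set_size_range[1] > set_size_range[2] ||
      set_size_range[1] < 1) {
    stop("'set_size_range' must be an increasing positive integer pair")
  }
  if (shift_from != round(shift_from) || shift_from < 1 ||
      shift_from > n_archetypes) {
    stop("'shift_from' must index an archetype")
  }
  cfg <- list(
    n_genes = as.integer(n_genes), n_archetypes = as.integer(n_archetypes),
    timepoints = timepoints, treatments = treatments,
    n_replicates = as.integer(n_replicates), tissues = tissues,
    frac_shifted = frac_shifted, shift_from = as.integer(shift_from),
    baseline_mean = baseline_mean, dispersion = dispersion,
    amplitude = amplitude, library_size_factors = library_size_factors,
    noise_sd = noise_sd, n_gene_sets = as.integer(n_gene_sets),
    set_size_range = as.integer(set_size_range),
    n_cell_types = as.integer(n_cell_types),
    signature_size = as.integer(signature_size), seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  cfg
}

## Orthonormal basis of the zero-mean subspace used to place archetypes:
## first two orthogonal polynomial contrasts over the timepoint index.
archetype_basis <- function(n_timepoints) {
  p <- stats::poly(seq_len(n_timepoints), degree = 2)
  list(u1 = p[, 1], u2 = p[, 2])
}

#' Generate distinct temporal archetype profiles
#'
#' Builds `n_archetypes` z-scored temporal trend shapes over the given
#' timepoints. A profile z-scored with the sample standard deviation lies on
#' a sphere of radius `sqrt(T - 1)` inside the zero-mean subspace;
#' archetypes are placed evenly on the circle spanned by the linear and
#' quadratic trend directions, starting at the monotone-up trend. Adjacent
#' shapes are therefore exactly `2 * sqrt(T - 1) * sin(pi / n)` apart, which
#' bounds how many shapes of a given minimum separation exist.
#'
#' @param n_archetypes number of shapes (>= 2).
#' @param timepoints ordered timepoint labels (length >= 3 for more than two
#'   shapes).
#' @param separation minimum pairwise Euclidean distance between shapes
#'   (z-score units).
#' @return numeric matrix (archetype x timepoint); each row has mean 0 and
#'   sample standard deviation 1. Rows carry descriptive shape names.
#' @export
generate_archetypes <- function(n_archetypes, timepoints, separation = 0.5) {
  n_tp <- length(timepoints)
  if (n_archetypes < 2) stop("'n_archetypes' must be >= 2")
  if (n_tp < 2) stop("need at least 2 timepoints")
  radius <- sqrt(n_tp - 1)
  if (n_tp == 2) {
    max_n <- 2L
  } else {
    ratio <- separation / (2 * radius)
    max_n <- if (ratio >= 1) 1L else as.integer(floor(pi / asin(ratio)))
  }
  if (n_archetypes > max_n) {
    stop(sprintf(
      "cannot construct %d distinct shapes over %d timepoints at separation %g; maximum is %d",
      n_archetypes, n_tp, separation, max_n
    ))
  }
  if (n_tp == 2) {
    arch <- rbind(c(-1, 1), c(1, -1)) / sqrt(2) * radius
  } else {
    b <- archetype_basis(n_tp)
    theta <- 2 * pi * (seq_len(n_archetypes) - 1) / n_archetypes
    arch <- radius * (outer(cos(theta), b$u1) + outer(sin(theta), b$u2))
  }
  canonical <- c("monotone_up", "late_up", "transient_dip", "early_down",
                 "monotone_down", "late_down", "transient_peak", "early_up")
  if (n_tp == 2) {
    labels <- c("monotone_up", "monotone_down")
  } else {
    idx <- (round(theta / (2 * pi) * 8) %% 8) + 1
    labels <- make.unique(canonical[idx], sep = "_")
  }
  rownames(arch) <- labels[seq_len(n_archetypes)]
  colnames(arch) <- paste0("t", timepoints)
  arch
}

## Premature-shift construction. The raw re-timed trend of archetype A is
## the step shape [A(t1), A(T), ..., A(T)]: the treated arm reaches its
## final control level already at the second timepoint. The planted
## inhibitor arm uses the shape of the archetype B nearest to that step
## shape (excluding A itself), with a constant log2 offset calibrated so
## the expected treated count at the second timepoint exactly equals the
## expected control count at the final timepoint. The offset changes level
## but not shape, so shifted genes belong to archetype B in z-score space.
shifted_step_shape <- function(archetype_row) {
  n <- length(archetype_row)
  c(archetype_row[1], rep(archetype_row[n], n - 1))
}

shift_target_archetype <- function(archetypes, from) {
  step <- shifted_step_shape(archetypes[from, ])
  step_z <- drop(zscore_rows(matrix(step, nrow = 1)))
  d <- sqrt(colSums((t(archetypes) - step_z)^2))
  d[from] <- Inf
  which.min(d)
}

build_sample_table <- function(config) {
  rows <- list()
  for (tissue in config$tissues) {
    for (tp_i in seq_along(config$timepoints)) {
      tp <- config$timepoints[tp_i]
      trts <- if (tp_i == 1L) config$treatments[1] else config$treatments
      for (trt in trts) {
        for (rep_i in seq_len(config$n_replicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sprintf("%s_t%s_%s_r%d", tissue, tp, trt, rep_i),
            tissue = tissue, timepoint_dpa = tp, treatment = trt,
            replicate = rep_i, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a negative-binomial time-course count matrix with ground truth
#'
#' Draws gene-level counts for the design described by `config`. Each gene
#' follows one temporal archetype; expected counts are
#' `library_size_factor * baseline_mean * 2^(amplitude * profile +
#' N(0, noise_sd))`, scaled further for planted cell-type signature genes,
#' and sampled negative-binomially with the configured dispersion
#' (`dispersion = 0` gives the deterministic rounded-mean limit). A fraction
#' `frac_shifted` of the genes assigned to archetype `shift_from` receive a
#' premature shift: under the inhibitor their expected level at the second
#' timepoint already equals their control level at the final timepoint. The
#' homeostatic first timepoint is simulated once per tissue and shared by
#' both treatment arms.
#'
#' @param config a [simulation_config()].
#' @return list with `counts` (integer matrix, genes x samples), `samples`
#'   (sample table data.frame), `gene_lengths` (named vector, nt), and
#'   `ground_truth` (archetype profiles, per-treatment archetype
#'   assignments, shifted gene ids, signature truth).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  arch <- generate_archetypes(config$n_archetypes, config$timepoints)
  samples <- build_sample_table(config)
  n_smp <- nrow(samples)
  genes <- sprintf("gene_%05d", seq_len(config$n_genes))
  sig <- generate_signatures(config)
  sig_genes <- unlist(sig$signatures, use.names = FALSE)
  n_shift <- as.integer(round(config$frac_shifted * config$n_genes))

  lib <- config$library_size_factors %||% rep(1, n_smp)
  lib <- rep_len(lib, n_smp)
  if (any(lib <= 0)) stop("library size factors must be positive")

  gt <- with_seed(config$seed, {
    lengths <- round(exp(stats::runif(config$n_genes, log(500), log(5000))))
    names(lengths) <- genes
    ## signature genes are flat (archetype NA); shifted genes are assigned
    ## to the source archetype first so the planted structure always
    ## exists, and the remaining genes get balanced random archetypes
    assignable <- setdiff(genes, sig_genes)
    if (n_shift > length(assignable)) {
      stop(sprintf(
        "cannot plant %d shifted genes among %d assignable genes",
        n_shift, length(assignable)
      ))
    }
    shifted <- sort(sample(assignable, n_shift))
    rest <- setdiff(assignable, shifted)
    arch_of <- c(
      stats::setNames(rep(config$shift_from, n_shift), shifted),
      stats::setNames(sample(rep_len(seq_len(config$n_archetypes),
                                     length(rest))), rest)
    )
    arch_of <- arch_of[assignable]
    list(lengths = lengths, arch_of = arch_of, shifted = shifted)
  })

  shift_to <- shift_target_archetype(arch, config$shift_from)
  ## log2 offset making the treated second-timepoint expected count equal
  ## the control final-timepoint expected count (shape unchanged)
  n_tp0 <- length(config$timepoints)
  shift_offset <- arch[config$shift_from, n_tp0] - arch[shift_to, 2]
  shift_prof <- arch[shift_to, ] + shift_offset

  ## per-(gene, treatment) log2 profile matrices over timepoints
  n_tp <- length(config$timepoints)
  prof_ctrl <- matrix(0, config$n_genes, n_tp, dimnames = list(genes, NULL))
  idx <- match(names(gt$arch_of), genes)
  prof_ctrl[idx, ] <- arch[gt$arch_of, , drop = FALSE]
  prof_inh <- prof_ctrl
  if (length(gt$shifted)) {
    prof_inh[match(gt$shifted, genes), ] <-
      matrix(shift_prof, length(gt$shifted), n_tp, byrow = TRUE)
  }

  counts <- matrix(0L, config$n_genes, n_smp,
                   dimnames = list(genes, samples$sample))
  mu_all <- with_seed(config$seed + 1L, {
    mu <- matrix(NA_real_, config$n_genes, n_smp)
    tp_idx <- match(samples$timepoint_dpa, config$timepoints)
    for (s in seq_len(n_smp)) {
      prof <- if (samples$treatment[s] == config$treatments[2]) prof_inh else prof_ctrl
      base_log2 <- config$amplitude * prof[, tp_idx[s]]
      noise <- if (config$noise_sd > 0) {
        stats::rnorm(config$n_genes, 0, config$noise_sd)
      } else 0
      mu[, s] <- lib[s] * config$baseline_mean * 2^(base_log2 + noise)
    }
    ## signature abundance multipliers scale expected counts per sample
    for (ct in names(sig$signatures)) {
      g <- match(sig$signatures[[ct]], genes)
      mu[g, ] <- mu[g, , drop = FALSE] *
        rep(sig$multipliers[ct, samples$sample], each = length(g))
    }
    mu
  })
  ## the homeostatic first timepoint exists once per tissue (control label
  ## only); downstream stages reuse it for both treatment arms
  counts[] <- with_seed(config$seed + 2L, {
    if (config$dispersion == 0) {
      round(mu_all)
    } else {
      matrix(
        stats::rnbinom(length(mu_all), mu = mu_all,
                       size = 1 / config$dispersion),
        nrow = config$n_genes
      )
    }
  })
  storage.mode(counts) <- "integer"

  gene_archetype <- data.frame(
    gene = genes,
    control = NA_integer_, inhibitor = NA_integer_,
    stringsAsFactors = FALSE
  )
  gene_archetype$control[idx] <- unname(gt$arch_of)
  gene_archetype$inhibitor <- gene_archetype$control
  gene_archetype$inhibitor[match(gt$shifted, genes)] <- shift_to

  ground_truth <- list(
    archetype_profiles = arch,
    gene_archetype = gene_archetype,
    shifted_genes = gt$shifted,
    shift_from = config$shift_from,
    shift_to = unname(shift_to),
    signature_truth = sig$multipliers,
    signatures = sig$signatures
  )
  list(counts = counts, samples = samples, gene_lengths = gt$lengths,
       ground_truth = ground_truth)
}

#' Generate gene-set collections with one planted enriched set
#'
#' Emits `config$n_gene_sets` gene sets: one "planted" set composed
#' predominantly (90%) of the generator's shifted genes, and decoy sets
#' drawn uniformly from non-shifted genes. Set sizes are drawn from
#' `config$set_size_range`.
#'
#' @param ground_truth the `ground_truth` element returned by
#'   [simulate_counts()].
#' @param config the matching [simulation_config()].
#' @return list with `sets` (named list of gene vectors) and `is_enriched`
#'   (named logical flags).
#' @export
generate_gene_sets <- function(ground_truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  genes <- ground_truth$gene_archetype$gene
  shifted <- ground_truth$shifted_genes
  other <- setdiff(genes, shifted)
  if (max(config$set_size_range) > length(genes)) {
    stop(sprintf("set sizes up to %d are infeasible with %d genes",
                 max(config$set_size_range), length(genes)))
  }
  with_seed(config$seed + 3L, {
    sizes <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
                    config$n_gene_sets, replace = TRUE)
    sets <- vector("list", config$n_gene_sets)
    names(sets) <- c("planted_shift_set",
                     sprintf("decoy_set_%02d", seq_len(config$n_gene_sets - 1L)))
    if (length(shifted) == 0) {
      stop("no shifted genes recorded; cannot plant an enriched set")
    }
    ## the planted set is 90% shifted genes; cap its size so that
    ## predominance is achievable with the available shifted genes
    sizes[1] <- min(sizes[1], floor(length(shifted) / 0.9))
    if (sizes[1] < config$set_size_range[1]) {
      stop(sprintf(
        "only %d shifted genes: cannot build a predominantly-shifted set of size >= %d",
        length(shifted), config$set_size_range[1]
      ))
    }
    n_core <- ceiling(0.9 * sizes[1])
    sets[[1]] <- sort(c(sample(shifted, n_core),
                        sample(other, sizes[1] - n_core)))
    for (i in seq_len(config$n_gene_sets - 1L)) {
      sets[[i + 1L]] <- sort(sample(other, sizes[i + 1L]))
    }
    is_enriched <- c(TRUE, rep(FALSE, config$n_gene_sets - 1L))
    names(is_enriched) <- names(sets)
    list(sets = sets, is_enriched = is_enriched)
  })
}

#' Generate disjoint cell-type signatures and true abundance multipliers
#'
#' Reserves the last `n_cell_types * signature_size` gene identifiers as
#' pairwise-disjoint signature lists and draws per-sample abundance
#' multipliers (`2^Uniform(-1.5, 1.5)`) that [simulate_counts()] applies to
#' the expected counts of the corresponding genes. Deterministic for a
#' given config, so standalone calls match the record embedded in the
#' generator's ground truth.
#'
#' @param config a [simulation_config()].
#' @return list with `signatures` (named list of gene id vectors) and
#'   `multipliers` (cell type x sample matrix of true multipliers).
#' @export
generate_signatures <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n_sig_genes <- config$n_cell_types * config$signature_size
  if (n_sig_genes > config$n_genes) {
    stop(sprintf("%d signature genes requested but only %d genes simulated",
                 n_sig_genes, config$n_genes))
  }
  samples <- build_sample_table(config)
  if (config$n_cell_types == 0L) {
    mult <- matrix(numeric(0), 0, nrow(samples),
                   dimnames = list(NULL, samples$sample))
    return(list(signatures = stats::setNames(list(), character(0)),
                multipliers = mult))
  }
  genes <- sprintf("gene_%05d", seq_len(config$n_genes))
  sig_genes <- utils::tail(genes, n_sig_genes)
  signatures <- split(sig_genes, rep(seq_len(config$n_cell_types),
                                     each = config$signature_size))
  names(signatures) <- sprintf("cell_type_%d", seq_len(config$n_cell_types))
  mult <- with_seed(config$seed + 4L, {
    m <- matrix(2^stats::runif(config$n_cell_types * nrow(samples), -1.5, 1.5),
                nrow = config$n_cell_types,
                dimnames = list(names(signatures), samples$sample))
    m
  })
  list(signatures = signatures, multipliers = mult)
}
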