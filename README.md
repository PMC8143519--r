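# clustershift

Temporal cluster-transition analysis for perturbed time-course RNA-seq.

## The problem

A short regeneration time course (homeostatic tissue at 0 days
post-amputation, wound healing at 3 dpa, blastema formation at 8 dpa) is
sequenced in two tissue compartments, with and without a perturbation such
as an HDAC inhibitor, at two replicates per condition. The question is not
which genes change, but which genes *change their timing*: a gene that
normally rises only at the blastema stage but is already elevated during
wound healing under the inhibitor has been prematurely activated.

`clustershift` detects such re-timing by:

1. **Normalization** — TMM-scaled log2-TPM from counts and gene lengths;
2. **Differential expression** — gene-wise least squares on a cell-means
   design with empirical-Bayes moderated t-statistics
   (t = c'β / (s̃ √(c'(X'X)⁻¹c)) on d₀ + d df, with
   s̃² = (d₀s₀² + d s²)/(d₀ + d)); genes with unadjusted p < 0.05 in ≥ 1
   of the six stage comparisons are "dynamic";
3. **Temporal clustering** — per arm, replicate-mean log2 profiles over
   (0, 3, 8) dpa are z-scored and both arms enter one fuzzy c-means fit
   (u_ij = 1/Σ_k(‖x_j−v_i‖/‖x_j−v_k‖)^{2/(m−1)}), with the cluster number
   chosen by the largest c whose minimum centroid distance stays above a
   threshold over a 4–27 scan;
4. **Transition matrix** — the row-stochastic matrix T with
   T[i, j] = fraction of control-cluster-i genes assigned to cluster j
   under treatment; off-diagonal cells are re-timed programs;
5. **Enrichment** — hypergeometric over-representation of gene sets in
   transition cells, and preranked GSEA on the signed log-p ranking
   sign(log2FC)·(−log10 p) with gene-label permutations;
6. **Cell abundance** — per-sample signature scores (arithmetic mean of
   marker-gene expression) as relative cell-type trajectories.

A negative-binomial synthetic-data generator with planted temporal
archetypes, premature-shift genes, enriched gene sets and signature
multipliers provides ground truth for every stage.

## Worked example

```r
library(clustershift)

cfg <- simulation_config(n_genes = 1000, tissues = "soft_tissue", seed = 42)
sim <- simulate_counts(cfg)

expr <- normalize_expression(sim$counts, sim$gene_lengths,
                             tmm_factors(sim$counts))
de      <- run_de(expr, sim$samples)
dynamic <- select_dynamic_genes(de$results)
length(dynamic)
#> [1] 968

profiles <- build_profiles(expr, sim$samples, dynamic)
model <- fuzzy_cmeans(profiles, c = 8, m = estimate_fuzzifier(profiles),
                      seed = 1)
tm <- compute_transition_matrix(model)
round(tm$proportions, 2)
#>      C1   C2   C3   C4   C5   C6   C7   C8
#> C1 1.00 0.00 0.00 0.00 0.00 0.00 0.00 0.00
#> C2 0.49 0.51 0.00 0.00 0.00 0.00 0.00 0.00
#> C3 0.01 0.00 0.89 0.00 0.10 0.00 0.00 0.00
#> C4 0.01 0.00 0.00 0.99 0.00 0.00 0.00 0.00
#> C5 0.00 0.00 0.00 0.00 0.99 0.00 0.01 0.00
#> C6 0.00 0.00 0.00 0.00 0.00 1.00 0.00 0.00
#> C7 0.00 0.00 0.00 0.00 0.00 0.00 0.95 0.05
#> C8 0.00 0.00 0.00 0.00 0.00 0.01 0.01 0.98
```

Nearly every cluster maps onto itself — temporal programs are mostly
stable under treatment — except row C2, where 49% of the genes moved to
cluster C1. Those are the planted premature-shift genes: this simulation
plants 10% of genes (100 of 1,000) as monotone-up under control but
early-up under the inhibitor, and the C2→C1 cell is exactly that
transition (cluster labels are canonical centroid order, so the planted
archetypes are located by nearest centroid):

```r
gt <- sim$ground_truth
cluster_of <- apply(gt$archetype_profiles, 1, function(a)
  which.min(colSums((t(model$centroids) - a)^2)))
cluster_of[c(gt$shift_from, gt$shift_to)]   # control archetype -> C2, target -> C1

shifted <- extract_transition_genes(model, cluster_of[gt$shift_from],
                                    cluster_of[gt$shift_to])
gs  <- generate_gene_sets(gt, cfg)
ora <- ora_hypergeometric(shifted, gs$sets, rownames(expr))
head(ora[, c("set", "overlap", "set_size", "p", "q")], 3)
#>                  set overlap set_size        p        q
#> 1  planted_shift_set      51       56 3.32e-51 6.64e-50
#> 6       decoy_set_05       1       30 9.61e-01 1.00e+00
#> 12      decoy_set_11       1       47 9.94e-01 1.00e+00
```

The gene set planted over the shifted genes tops the over-representation
ranking of the transition cell at q ≈ 7e-50; decoy sets are null.

The whole chain — including the cluster-number scan, stage-wise GSEA and
abundance scoring, with every intermediate written as TSV plus a
checksummed manifest — runs from one config:

```r
cfg <- read_pipeline_config(system.file("extdata", "fixture_config.yaml",
                                        package = "clustershift"))
run_pipeline(cfg, out_dir = "pipeline_out")
```

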