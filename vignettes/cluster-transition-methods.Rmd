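---
title: "Detecting treatment-induced re-timing of temporal expression programs"
author: "clustershift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting treatment-induced re-timing of temporal expression programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustershift)
```

## The scientific question

Regenerating tissue moves through stereotyped transcriptional stages — in
an amputated axolotl limb, wound healing around 3 days post-amputation
(dpa) and blastema formation from about 8 dpa. A perturbation (here, a
histone-deacetylase inhibitor applied to the amputation site) may not
simply switch genes on or off: it can *re-time* a gene's temporal program,
so that a gene which should rise only at the blastema stage is already
elevated during wound healing. `clustershift` provides the analysis chain
that detects such premature shifts from a short bulk RNA-seq time course
with control and treated arms: each gene's temporal trajectory is reduced
to a shape, shapes are clustered jointly across both arms, and a
cluster-transition matrix summarizes which temporal programs moved where
under the treatment.

The experimental design the package targets is small and fixed in
structure: two tissue compartments (wound epidermis and underlying soft
tissue), three timepoints (0, 3, 8 dpa), two arms (vehicle control and
inhibitor) and two pooled replicates per condition, with the 0-dpa
homeostatic sample shared by both arms. Tissues are analyzed as
independent arms throughout.

## Pipeline and model choices

### Normalization

Counts are converted to transcripts-per-million using gene effective
lengths, with the library size in the TPM denominator scaled by a
trimmed-mean-of-M-values (TMM) factor; expression is reported as
`log2(TPM + 1)`. The TMM factor follows the standard procedure: the
reference sample is the one whose upper-quartile count proportion is
closest to the mean; M-values are trimmed 30% two-sided and A-values 5%
two-sided; retained M-values are combined with inverse-binomial-variance
weights; factors are rescaled to geometric mean 1. These trim fractions
and the precision weighting are the published defaults of the method. The
pseudocount of 1 before the log is required because zeros are common at
this sequencing depth; it is configurable.

Whether TMM should rescale counts or the TPM denominator is genuinely
ambiguous in this design; the package multiplies the sample's library size
inside the TPM denominator and records that choice in the expression
matrix's provenance attribute.

### Differential expression and the dynamic-gene filter

Each tissue's samples are modeled per gene by ordinary least squares on a
cell-means design with five groups (`t0`, `t3_control`, `t8_control`,
`t3_inhibitor`, `t8_inhibitor`), so coefficients are group means and, with
two replicates per group, each gene has 5 residual degrees of freedom.
Gene-wise variances are moderated by an empirical-Bayes scaled
inverse-chi-square prior whose hyperparameters `(d0, s0^2)` are estimated
by moment matching on `log s^2`; the posterior variance
`(d0 s0^2 + d s^2) / (d0 + d)` feeds a moderated t-statistic on `d0 + d`
degrees of freedom. This augmentation matters at n = 2 replicates: without
it, single-gene variance estimates on 5 df make both false positives and
false negatives erratic.

A gene is *dynamic* if its unadjusted p-value falls below 0.05 in at least
one of the six stage comparisons (3 vs 0, 8 vs 0, 8 vs 3 dpa, under each
arm). The filter deliberately uses unadjusted p-values — it is a recall
filter feeding an unsupervised step, not an inference; multiplicity
control is applied later, in enrichment testing. All six comparisons are
used, including 8 vs 3, even though stage contrasts against 0 dpa
dominate downstream interpretation.

### Temporal profiles and fuzzy clustering

For every dynamic gene and each arm, replicate log2 values are averaged
per timepoint (the 0-dpa mean is shared by both arms) and the resulting
3-point profile is z-scored with the sample standard deviation. Replicate
means, not individual replicates, are clustered: the object of interest is
the trajectory shape, and with n = 2 the replicate scatter would otherwise
dominate the shape space. A z-scored 3-point profile has two free
dimensions — it lies on a circle of radius sqrt(2) in the zero-mean plane —
which is why a handful of trend shapes (monotone up/down, early/late
up/down, transient peak/dip) tile this space.

Both arms of every gene enter one matrix and a *single* fuzzy c-means fit,
so control and treated trajectories are assigned in a shared centroid
space; transitions are then comparisons of assignments within one model,
never a matching problem between two separately fitted clusterings.

Fuzzy c-means uses the standard alternating membership/centroid updates
with fuzzifier `m` estimated from the data dimensions by the usual
empirical formula (for ~2,000 rows and 3 timepoints, `m` is around 3.6).
Initialization is k-means++-style seeding (first centroid uniform, later
centroids sampled proportionally to squared distance from the nearest
chosen one): uniform row sampling almost never covers all modes of tightly
clustered data — with 8 tight clouds the probability that 8 uniform draws
hit all 8 is below 1% — and the best of 3 seeded restarts by the objective
`J` is kept. Convergence is declared when the largest membership change
falls below 1e-6 (at most 200 iterations); `J` is non-increasing across
iterations by construction and this is asserted in the tests. Rows are
processed in identifier order so results are invariant to row permutation,
and cluster labels are canonicalized by sorting centroids
lexicographically over timepoint values, making cluster numbering
reproducible. Hard assignments are the membership argmax with ties to the
lowest cluster index; no minimum-membership cutoff is applied, but
memberships are exported for users who want one.

### Choosing the number of clusters

For each candidate `c` in 4–27 the model is refitted and the minimum
pairwise centroid distance `d_min(c)` recorded. Once `c` exceeds the
number of genuinely distinct shapes, at least two centroids end up
describing one cloud and `d_min` collapses; the chosen `c` is the largest
candidate with `d_min(c) > theta`. The default `theta = 0.3` (z-score
units) was set from the geometry of the two regimes: duplicated centroids
within one cloud sit roughly a within-cluster spread apart (empirically
below ~0.16 under realistic noise), while distinct trend shapes worth
resolving are at least ~0.5 apart (the archetype generator's separation
floor; 8 evenly spaced shapes are ~1.08 apart). A threshold below the
duplicate-centroid scale — say 0.1 — fails to cut the collapsed regime and
systematically over-selects `c`; any value in the (0.16, 0.5) band behaves
equivalently, and `theta` remains exposed in the pipeline configuration.
An explicit `clusters` override reproduces a fixed-`c` analysis such as
the canonical 8-cluster solution.

### Transition matrix

For genes with both arms assigned, `counts[i, j]` is the number of genes
in control cluster `i` and treated cluster `j`; rows are normalized to
proportions. Off-diagonal mass is the signal: cell `(i, j)` collects genes
whose temporal program changed from shape `i` to shape `j` under
treatment. Per-cell gene lists feed over-representation analysis, and
empty control clusters are flagged rather than dropped so the matrix shape
is stable.

### Enrichment

Gene rankings for preranked GSEA use the signed log-p score
`sign(log2FC) * (-log10 p)` from one contrast, with ties broken by
absolute fold change and then gene identifier; p = 0 is clamped to the
smallest representable double. The enrichment score is the classic
weighted Kolmogorov–Smirnov running sum with weight exponent 1. The null
is built by randomizing set membership (gene-label permutation) — with two
replicates per group, phenotype permutation is impossible — and
`NES = ES / mean(|null ES| of the same sign)`. Nominal p-values use the
add-one correction; FDR q follows the sign-stratified NES tail-ratio
procedure with a BH-style step-up pass so q is monotone in |NES|.
Over-representation analysis is the exact upper-tail hypergeometric test
with BH adjustment across sets. Enrichment maps connect significant sets
(q < 0.05) whose Jaccard similarity over the measured universe reaches
0.25 (overlap coefficient available as an option); both cutoffs are
configurable.

### Cell-type abundance scores

A cell type's abundance proxy in a sample is the arithmetic mean of its
signature genes' normalized expression. The package averages the
pipeline's log2-TPM values (a linear-scale matrix can be supplied
instead — the underlying publication-style description of "normalized read
counts" is ambiguous on this point), applies no gene weighting, and offers
per-type z-scoring across samples for display. These scores are relative
trajectories, not compositional estimates: no deconvolution is attempted.

## The synthetic-data generator

The generator is first-class, tested code; it defines the conditions under
which the pipeline's claims are validated.

* **Design**: 2 tissues x (0, 3, 8) dpa x (control, inhibitor) x 2
  replicates, with 0 dpa simulated once per tissue and shared by both
  arms. Replicates are i.i.d. — the within-pool variance structure of
  pooled animal replicates is unknowable from the outside.
* **Counts**: negative-binomial with mean
  `lib_factor * baseline_mean * 2^(amplitude * archetype + N(0, noise_sd))`
  and gene-shared dispersion. Defaults: baseline mean 100 (a mid-depth
  bulk library), dispersion 0.05 (typical bulk biological replication),
  log2 noise sd 0.25, amplitude 2 log2 units. `dispersion = 0` gives a
  deterministic rounded-mean limit used by exact tests.
* **Archetypes**: `n` z-scored trend shapes placed evenly on the circle of
  z-scored 3-point profiles, starting at the monotone-up trend; the
  minimum pairwise distance is `2 sqrt(2) sin(pi / n)` in closed form, and
  requests beyond the constructible maximum for a given separation raise
  an error naming that maximum.
* **Premature shifts**: a configurable fraction of genes follow archetype
  A under control; under the inhibitor they follow the shape of the
  archetype B nearest to the re-timed step trend `[A(0), A(8), A(8)]`,
  with a constant log2 offset calibrated so the treated 3-dpa expected
  count exactly equals the control 8-dpa expected count. The offset moves
  level, not shape, so shifted genes belong to archetype B in z-score
  space and the ground truth can record a well-defined A-to-B transition.
* **Gene lengths**: log-uniform in [500, 5000] nt, so TPM and CPM differ
  and the length-normalization path is genuinely exercised.
* **Gene sets**: one planted set that is 90% shifted genes plus uniform
  decoy sets from non-shifted genes; **signatures**: disjoint per-type
  gene lists whose expected counts are scaled per sample by recorded
  multipliers `2^U(-1.5, 1.5)`.

What the generator does **not** emulate: batch effects, library-prep
composition biases beyond what TMM corrects by construction, correlated
genes within pathways, isoform structure, or single-cell resolution.
Passing the packaged validations therefore demonstrates that the
implementation recovers the structure it models — not that real tissue
data will be as clean; in particular real cluster boundaries are soft and
real transition cells far noisier than the planted ones.

## Validation conditions and problem sizes

The packaged checks run at sizes chosen to exercise every code path while
keeping a full run in minutes: premature-shift recovery on 2,000 genes
with 200 planted shifts at noise sd 0.25 (recovery of the planted
transition cell ~99%, planted set first in ORA at q << 0.05);
cluster-number selection on 360 genes from 8 archetypes at noise sd 0.1
(4–27 scan, 20 seeds); moderated-t calibration on 5,000 null genes
(rejection ~5% at p < 0.05 per contrast); enrichment-score equivalence
against a brute-force running sum at 1e-12 on randomized lists; exact
hypergeometric enumeration for all universes up to 12; TMM equality with
the published reference implementation on a composition-biased toy; and
bit-reproducibility of the full pipeline from one config and seed.

## Numerical conventions and degenerate inputs

* z-scores use the sample (n-1) standard deviation everywhere; rows with
  sd below 1e-12 become all-zero and are flagged (QC heatmap, abundance)
  or dropped with a report (temporal profiles, where a flat profile has no
  shape).
* A profile exactly coincident with a centroid receives full membership in
  the first coincident centroid.
* An all-zero sample is an error for TMM (no library) but a legal all-zero
  column for TPM.
* Samples sharing no expressed genes with the TMM reference get factor 1
  with a warning.
* `d0 = Inf` (no excess variance spread) and forced `d0 = 0` (no
  moderation) are both supported limits of the moderated test.
* Ties in hard assignment break to the lowest cluster index; ranking ties
  break by |log2FC| then gene identifier; all stochastic steps take
  explicit seeds and the pipeline derives stage seeds deterministically
  from the config seed.

## Known limitations

* With 2 replicates per group, power at gene level is modest and the
  dynamic-gene filter at p < 0.05 is liberal by design; downstream
  conclusions should rest on transition-level enrichment, not single
  genes.
* The 3-point profile space cannot distinguish shapes that differ only
  between sampled timepoints; "premature" here means specifically
  "8-dpa-like at 3 dpa".
* Gene-label permutation GSEA tests a competitive null and ignores
  inter-gene correlation; q-values on strongly correlated sets are
  anti-conservative in real data.
* Signature scores are relative abundance proxies; they cannot separate
  per-cell expression change from composition change.
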