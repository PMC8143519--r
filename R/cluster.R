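#' Merged control/treatment temporal profiles for clustering
#'
#' For every dynamic gene and each treatment arm, averages replicate log2
#' expression per timepoint (the shared homeostatic baseline mean is reused
#' for both arms) and z-scores the resulting short profile with the sample
#' standard deviation. Both arms of a gene enter one matrix so that a
#' single clustering fit places control and treatment trajectories in a
#' shared centroid space. Genes with a zero-variance profile in either arm
#' are dropped (both rows) and reported.
#'
#' @param expr expression matrix (genes x samples), log2 scale.
#' @param samples single-tissue sample table.
#' @param genes character vector of (dynamic) gene identifiers to profile.
#' @param treatments treatment labels; the first is the arm carrying the
#'   baseline timepoint.
#' @return object of class `"temporal_profiles"`: list with `profiles`
#'   (rows = gene x treatment, columns = timepoints, z-scored), `meta`
#'   (data.frame gene/treatment per row) and `dropped` (gene identifiers
#'   removed for zero variance).
#' @export
build_profiles <- function(expr, samples, genes,
                           treatments = c("control", "inhibitor")) {
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    stop("gene(s) absent from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  tps <- sort(unique(samples$timepoint_dpa))
  base_tp <- tps[1]
  mean_at <- function(tp, trt) {
    sel <- samples$sample[samples$timepoint_dpa == tp &
                            samples$treatment == trt]
    if (tp == base_tp && length(sel) == 0) {
      sel <- samples$sample[samples$timepoint_dpa == tp]
    }
    if (length(sel) == 0) {
      stop(sprintf("no samples at timepoint %s, treatment %s", tp, trt))
    }
    rowMeans(expr[genes, sel, drop = FALSE])
  }
  base_mean <- rowMeans(expr[genes,
                             samples$sample[samples$timepoint_dpa == base_tp],
                             drop = FALSE])
  arm <- function(trt) {
    m <- vapply(tps[-1], function(tp) mean_at(tp, trt),
                numeric(length(genes)))
    cbind(base_mean, m)
  }
  raw <- do.call(rbind, lapply(treatments, arm))
  meta <- data.frame(
    gene = rep(genes, times = length(treatments)),
    treatment = rep(treatments, each = length(genes)),
    stringsAsFactors = FALSE
  )
  z <- zscore_rows(raw)
  const_rows <- attr(z, "constant_rows")
  dropped_genes <- unique(meta$gene[const_rows])
  keep <- !(meta$gene %in% dropped_genes)
  if (length(dropped_genes)) {
    message(length(dropped_genes),
            " gene(s) dropped for zero-variance temporal profile")
  }
  profiles <- z[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  rownames(profiles) <- paste(meta$gene, meta$treatment, sep = "|")
  colnames(profiles) <- paste0("t", tps)
  structure(list(profiles = profiles, meta = meta, dropped = dropped_genes),
            class = "temporal_profiles")
}

#' Data-driven fuzzifier estimate
#'
#' Empirical formula for the fuzzy c-means fuzzifier `m` as a function of
#' the number of profiles `N` and dimensions `D`:
#' `m = 1 + (1418/N + 22.05) * D^-2 +
#' (12.33/N + 0.243) * D^(-0.0406 * ln N - 0.1134)`.
#'
#' @param profiles a [build_profiles()] object or numeric matrix.
#' @return fuzzifier `m > 1`.
#' @export
estimate_fuzzifier <- function(profiles) {
  x <- if (inherits(profiles, "temporal_profiles")) profiles$profiles else profiles
  n <- nrow(x)
  d <- ncol(x)
  if (d < 2) stop("need at least 2 profile dimensions")
  if (n < 10) stop("need at least 10 profiles")
  1 + (1418 / n + 22.05) * d^-2 +
    (12.33 / n + 0.243) * d^(-0.0406 * log(n) - 0.1134)
}

## k-means++ seeding: first centroid sampled uniformly, each further one
## with probability proportional to squared distance from the nearest
## centroid chosen so far. Spreads initial centroids across the data's
## modes far more reliably than uniform row sampling.
kmeanspp_init <- function(x, c) {
  n <- nrow(x)
  idx <- integer(c)
  idx[1] <- sample.int(n, 1)
  d2 <- colSums((t(x) - x[idx[1], ])^2)
  for (i in seq_len(c - 1L)) {
    if (all(d2 == 0)) {
      idx[i + 1L] <- sample.int(n, 1)
    } else {
      idx[i + 1L] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, colSums((t(x) - x[idx[i + 1L], ])^2))
  }
  x[idx, , drop = FALSE]
}

## One fuzzy c-means run from given initial centroids. Returns centroids,
## memberships, per-iteration objective and iteration count.
fcm_once <- function(x, centroids, m, max_iter = 200, tol = 1e-6) {
  n <- nrow(x)
  cc <- nrow(centroids)
  exp_u <- 2 / (m - 1)
  u_prev <- NULL
  j_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    d2 <- outer(rowSums(x^2), rep(1, cc)) - 2 * x %*% t(centroids) +
      outer(rep(1, n), rowSums(centroids^2))
    d2[d2 < 0] <- 0
    zero <- d2 < 1e-24
    inv <- d2^(-exp_u / 2)
    u <- inv / rowSums(inv)
    hit <- which(rowSums(zero) > 0)
    for (r in hit) {  # coincident point: full membership to first match
      u[r, ] <- 0
      u[r, which(zero[r, ])[1]] <- 1
    }
    um <- u^m
    centroids <- (t(um) %*% x) / colSums(um)
    d2 <- outer(rowSums(x^2), rep(1, cc)) - 2 * x %*% t(centroids) +
      outer(rep(1, n), rowSums(centroids^2))
    d2[d2 < 0] <- 0
    j_trace <- c(j_trace, sum(um * d2))
    if (!is.null(u_prev) && max(abs(u - u_prev)) < tol) break
    u_prev <- u
  }
  list(centroids = centroids, membership = u, j_trace = j_trace,
       iterations = iter)
}

#' Fuzzy c-means clustering of temporal profiles
#'
#' Alternating-update fuzzy c-means with seeded multi-restart
#' initialization. Rows are processed in identifier order so the result is
#' invariant to input row permutations; cluster labels are canonicalized by
#' sorting centroids lexicographically over the timepoint values, making
#' numbering reproducible across runs. Convergence when the largest
#' membership change falls below `tol` or after `max_iter` iterations; the
#' restart with the lowest objective `J = sum_ij u_ij^m ||x_j - v_i||^2`
#' wins.
#'
#' @param profiles a [build_profiles()] object or numeric matrix with
#'   unique row names.
#' @param c number of clusters (>= 2, <= rows).
#' @param m fuzzifier (> 1); see [estimate_fuzzifier()].
#' @param seed integer seed for the restart initializations.
#' @param restarts number of seeded initializations.
#' @param max_iter,tol convergence controls.
#' @return object of class `"cluster_model"`: `centroids` (c x timepoints),
#'   `membership` (rows x c, rows sum to 1), `assignment` (argmax
#'   membership, ties to the lowest index), `objective`, `j_trace`,
#'   `iterations`, `m`, `seed`, and the profile `meta` when available.
#' @export
fuzzy_cmeans <- function(profiles, c, m, seed = 1L, restarts = 3L,
                         max_iter = 200L, tol = 1e-6) {
  meta <- NULL
  if (inherits(profiles, "temporal_profiles")) {
    meta <- profiles$meta
    x <- profiles$profiles
  } else {
    x <- as.matrix(profiles)
  }
  if (c < 2) stop("'c' must be >= 2")
  if (m <= 1) stop("fuzzifier 'm' must be > 1")
  if (c > nrow(x)) stop("more clusters than profiles")
  if (is.null(rownames(x))) rownames(x) <- sprintf("row_%06d", seq_len(nrow(x)))
  ord <- order(rownames(x))
  xs <- x[ord, , drop = FALSE]
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- with_seed(seed + r - 1L, kmeanspp_init(xs, c))
    run <- fcm_once(xs, init, m, max_iter = max_iter, tol = tol)
    if (is.null(best) || utils::tail(run$j_trace, 1) <
        utils::tail(best$j_trace, 1)) {
      best <- run
    }
  }
  ## canonical labels: lexicographic centroid order over timepoints
  canon <- do.call(order, as.data.frame(best$centroids))
  centroids <- best$centroids[canon, , drop = FALSE]
  u_sorted <- best$membership[, canon, drop = FALSE]
  ## map back to the caller's row order
  u <- matrix(NA_real_, nrow(x), c,
              dimnames = list(rownames(x), paste0("cluster_", seq_len(c))))
  u[rownames(xs), ] <- u_sorted
  rownames(centroids) <- paste0("cluster_", seq_len(c))
  colnames(centroids) <- colnames(x)
  assignment <- max.col(u, ties.method = "first")
  names(assignment) <- rownames(x)
  structure(list(
    c = c, m = m, centroids = centroids, membership = u,
    assignment = assignment, objective = utils::tail(best$j_trace, 1),
    j_trace = best$j_trace, iterations = best$iterations, seed = seed,
    meta = meta
  ), class = "cluster_model")
}

#' Cluster-number selection by the minimum-centroid-distance scan
#'
#' Fits fuzzy c-means for every candidate cluster count and records the
#' minimum pairwise Euclidean distance between centroids, `d_min(c)`. As
#' `c` exceeds the number of genuinely distinct temporal shapes, extra
#' centroids nearly coincide and `d_min` collapses; the chosen `c` is the
#' largest candidate with `d_min(c) > theta`.
#'
#' @param profiles a [build_profiles()] object or matrix.
#' @param m fuzzifier.
#' @param c_range inclusive candidate range (default 4 to 27).
#' @param theta minimum-centroid-distance threshold in z-score units.
#' @param seed integer seed.
#' @param restarts restarts per candidate fit.
#' @return list of class `"cluster_scan"` with `scan` (data.frame `c`,
#'   `d_min`), `chosen`, `theta`.
#' @export
select_cluster_number <- function(profiles, m, c_range = c(4, 27),
                                  theta = 0.3, seed = 1L, restarts = 3L) {
  x <- if (inherits(profiles, "temporal_profiles")) profiles$profiles else profiles
  cs <- seq(c_range[1], c_range[2])
  if (min(cs) < 2 || max(cs) > nrow(x) - 1) {
    stop("cluster range must lie within [2, rows - 1]")
  }
  d_min <- vapply(cs, function(cc) {
    fit <- fuzzy_cmeans(profiles, c = cc, m = m, seed = seed + 1000L * cc,
                        restarts = restarts)
    min(stats::dist(fit$centroids))
  }, numeric(1))
  feasible <- cs[d_min > theta]
  if (length(feasible) == 0) {
    warning("no candidate exceeds theta = ", theta,
            "; falling back to the smallest candidate")
    chosen <- min(cs)
  } else {
    chosen <- max(feasible)
  }
  structure(list(scan = data.frame(c = cs, d_min = d_min),
                 chosen = chosen, theta = theta),
            class = "cluster_scan")
}
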