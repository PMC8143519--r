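#' Signed log-p gene ranking for preranked GSEA
#'
#' Ranks the genes of one contrast by `r = -log10(p)` for genes with fold
#' change above 1 and `r = +log10(p)` otherwise, i.e.
#' `sign(log2FC) * (-log10 p)`. Ties are broken by `|log2FC|` (descending)
#' and then by gene identifier so the order is deterministic. Zero
#' p-values are clamped to the smallest representable double with a
#' warning.
#'
#' @param de one contrast's data.frame with columns `gene`, `log2FC`, `p`.
#' @return data.frame (`gene`, `score`) in descending score order.
#' @export
rank_genes <- function(de) {
  if (!all(c("gene", "log2FC", "p") %in% colnames(de))) {
    stop("need columns gene, log2FC, p")
  }
  if (any(!is.finite(de$log2FC))) stop("missing or non-finite fold change")
  p <- de$p
  if (any(p <= 0)) {
    warning("p-value(s) of 0 clamped to machine minimum")
    p[p <= 0] <- .Machine$double.xmin
  }
  score <- ifelse(de$log2FC > 0, -log10(p), log10(p))
  ord <- order(-score, -abs(de$log2FC), de$gene)
  out <- data.frame(gene = de$gene[ord], score = score[ord],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene)) stop("duplicate genes in ranking input")
  out
}

#' Weighted running-sum enrichment score
#'
#' The classic weighted Kolmogorov-Smirnov statistic: walking down the
#' ranked list, set members ("hits") add `|r|^p_exp / N_R` (with `N_R` the
#' sum of hit weights) and non-members subtract `1 / (N - N_H)`. The
#' enrichment score is the signed maximum deviation of this running sum
#' from zero; the leading edge contains the hits at or before the positive
#' extremum (at or after the negative extremum for negative ES).
#'
#' @param ranked a [rank_genes()] data.frame (or named score vector,
#'   descending).
#' @param set character vector of member genes.
#' @param p_exp weight exponent (1 = classic weighted statistic).
#' @return list with `es`, `running` (length-N running sum) and
#'   `leading_edge`.
#' @export
gsea_es <- function(ranked, set, p_exp = 1) {
  if (is.data.frame(ranked)) {
    scores <- stats::setNames(ranked$score, ranked$gene)
  } else {
    scores <- ranked
  }
  n <- length(scores)
  hit <- names(scores) %in% set
  n_hit <- sum(hit)
  if (n_hit == 0) stop("set does not intersect the ranked universe")
  if (n_hit == n) {
    w <- abs(scores)^p_exp
    nr <- sum(w)
    running <- if (nr > 0) cumsum(w) / nr else cumsum(rep(1 / n, n))
    return(list(es = max(running), running = running,
                leading_edge = names(scores)))
  }
  w <- abs(scores)^p_exp
  nr <- sum(w[hit])
  steps <- numeric(n)
  if (nr > 0) {
    steps[hit] <- w[hit] / nr
  } else {
    steps[hit] <- 1 / n_hit  # all-zero hit weights: equal mass
  }
  steps[!hit] <- -1 / (n - n_hit)
  running <- cumsum(steps)
  i_max <- which.max(running)
  i_min <- which.min(running)
  es <- if (abs(running[i_max]) >= abs(running[i_min])) {
    running[i_max]
  } else {
    running[i_min]
  }
  leading <- if (es >= 0) {
    names(scores)[seq_len(i_max)][hit[seq_len(i_max)]]
  } else {
    names(scores)[i_min:n][hit[i_min:n]]
  }
  list(es = es, running = running, leading_edge = leading)
}

## ES evaluated only at hit positions -- used for permutations. `pos` are
## sorted hit positions in 1..n, `w` the full weight vector.
es_at_positions <- function(pos, w, n, nr = sum(w[pos])) {
  k <- length(pos)
  miss_step <- 1 / (n - k)
  cum_hit <- if (nr > 0) cumsum(w[pos]) / nr else cumsum(rep(1 / k, k))
  at_hit <- cum_hit - (pos - seq_len(k)) * miss_step
  before_hit <- c(0, cum_hit[-k]) - (pos - seq_len(k)) * miss_step
  hi <- max(at_hit)
  lo <- min(c(before_hit, 0))  # the running sum always returns to 0 at n
  if (abs(hi) >= abs(lo)) hi else lo
}

#' Preranked GSEA with gene-label permutations
#'
#' Computes the weighted running-sum enrichment score of every set against
#' a signed log-p ranking and assesses it against a null built by
#' randomizing set membership (set sizes preserved), which is appropriate
#' when replicate counts are too small for phenotype permutation.
#' `NES = ES / mean(|null ES| of the same sign)`; the nominal p is the
#' add-one-corrected fraction of same-sign null scores at least as
#' extreme; FDR q follows the standard NES-based tail-ratio procedure
#' (sign-stratified, clipped to `[0, 1]`, monotone in |NES|).
#'
#' @param ranked a [rank_genes()] data.frame.
#' @param sets named list of gene vectors.
#' @param n_perm number of membership permutations (>= 100).
#' @param seed integer seed.
#' @param p_exp weight exponent.
#' @return data.frame per set: `set`, `size`, `es`, `nes`, `p`, `q`,
#'   `leading_edge` (comma-separated), sorted by `p`.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000L, seed = 1L,
                           p_exp = 1) {
  if (n_perm < 100) stop("need n_perm >= 100")
  universe <- ranked$gene
  n <- length(universe)
  w <- abs(ranked$score)^p_exp
  restricted <- lapply(sets, intersect, universe)
  sizes <- vapply(restricted, length, 1L)
  skip <- sizes == 0
  if (any(skip)) {
    message(sum(skip), " set(s) with empty universe intersection skipped")
  }
  if (any(sizes > n)) stop("set larger than the ranked universe")
  keep <- names(sets)[!skip]
  if (length(keep) == 0) {
    return(data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p = numeric(0), q = numeric(0),
                      leading_edge = character(0), stringsAsFactors = FALSE))
  }
  obs <- lapply(restricted[keep], function(s) gsea_es(ranked, s, p_exp))
  es_obs <- vapply(obs, `[[`, numeric(1), "es")

  null_by_size <- new.env(parent = emptyenv())
  null_for <- function(k) {
    key <- as.character(k)
    if (!is.null(null_by_size[[key]])) return(null_by_size[[key]])
    vals <- vapply(seq_len(n_perm), function(i) {
      pos <- sort.int(sample.int(n, k))
      es_at_positions(pos, w, n)
    }, numeric(1))
    null_by_size[[key]] <- vals
    vals
  }
  res <- with_seed(seed, {
    nes <- numeric(length(keep))
    pval <- numeric(length(keep))
    null_nes_all <- vector("list", length(keep))
    for (i in seq_along(keep)) {
      k <- length(restricted[[keep[i]]])
      nulls <- null_for(k)
      pos_mean <- mean(nulls[nulls >= 0])
      neg_mean <- mean(abs(nulls[nulls < 0]))
      if (!is.finite(pos_mean) || pos_mean == 0) pos_mean <- NA_real_
      if (!is.finite(neg_mean) || neg_mean == 0) neg_mean <- NA_real_
      e <- es_obs[i]
      if (e >= 0) {
        same <- nulls[nulls >= 0]
        nes[i] <- if (is.na(pos_mean)) 0 else e / pos_mean
        pval[i] <- (1 + sum(same >= e)) / (1 + length(same))
      } else {
        same <- nulls[nulls < 0]
        nes[i] <- if (is.na(neg_mean)) 0 else e / neg_mean
        pval[i] <- (1 + sum(same <= e)) / (1 + length(same))
      }
      null_nes_all[[i]] <- c(
        if (!is.na(pos_mean)) nulls[nulls >= 0] / pos_mean else numeric(0),
        if (!is.na(neg_mean)) nulls[nulls < 0] / neg_mean else numeric(0)
      )
    }
    list(nes = nes, pval = pval, null_nes = unlist(null_nes_all))
  })
  q <- gsea_fdr(res$nes, res$null_nes)
  out <- data.frame(
    set = keep, size = sizes[keep], es = unname(es_obs), nes = res$nes,
    p = res$pval, q = q,
    leading_edge = vapply(obs, function(o) {
      paste(o$leading_edge, collapse = ",")
    }, ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$p, -abs(out$nes)), , drop = FALSE]
}

## Sign-stratified NES tail-ratio FDR with monotone cleanup.
gsea_fdr <- function(nes_obs, nes_null) {
  q <- rep(NA_real_, length(nes_obs))
  for (i in seq_along(nes_obs)) {
    v <- nes_obs[i]
    if (v >= 0) {
      num_pool <- nes_null[nes_null >= 0]
      obs_pool <- nes_obs[nes_obs >= 0]
      num <- if (length(num_pool)) mean(num_pool >= v) else 0
      den <- mean(obs_pool >= v)
    } else {
      num_pool <- nes_null[nes_null < 0]
      obs_pool <- nes_obs[nes_obs < 0]
      num <- if (length(num_pool)) mean(num_pool <= v) else 0
      den <- mean(obs_pool <= v)
    }
    q[i] <- if (den > 0) min(1, num / den) else 0
  }
  ## step-up monotonicity within each sign: a set's q is the smallest
  ## tail-ratio estimate over all thresholds that still include it
  ## (i.e. over sets no more extreme), as in BH
  for (sgn in c(1, -1)) {
    idx <- if (sgn > 0) which(nes_obs >= 0) else which(nes_obs < 0)
    if (length(idx) > 1) {
      ord <- idx[order(-abs(nes_obs[idx]))]  # most extreme first
      q[ord] <- rev(cummin(rev(q[ord])))
    }
  }
  q
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of each set's overlap with a query list
#' against a gene universe, with Benjamini-Hochberg adjustment across
#' sets. Query genes outside the universe are dropped with a message.
#'
#' @param query character vector of query genes (e.g. one transition's
#'   gene list).
#' @param sets named list of gene vectors.
#' @param universe character vector of measured genes.
#' @return data.frame per set: `set`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p`, `q`, sorted by `p`.
#' @export
ora_hypergeometric <- function(query, sets, universe) {
  universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    message(length(outside), " query gene(s) outside the universe dropped")
  }
  query <- unique(intersect(query, universe))
  if (length(query) == 0) stop("query is empty after universe restriction")
  n_u <- length(universe)
  n_q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    set_u <- intersect(unique(sets[[nm]]), universe)
    k_set <- length(set_u)
    if (k_set == 0) return(NULL)
    k <- length(intersect(set_u, query))
    p <- stats::phyper(k - 1, k_set, n_u - k_set, n_q, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = k_set, query_size = n_q,
               universe_size = n_u, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no set intersects the universe")
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$set), , drop = FALSE]
}

#' Enrichment-map graph of significant gene sets
#'
#' Nodes are the sets passing the significance filter; an undirected edge
#' joins two sets whose universe-restricted members are similar enough
#' (Jaccard by default).
#'
#' @param results a [gsea_preranked()] or [ora_hypergeometric()] table
#'   carrying `set` and `q` (and optionally `nes`).
#' @param sets the named list of gene sets behind the results.
#' @param universe measured-gene universe for restriction.
#' @param q_cut significance cutoff on `q`.
#' @param sim_cut minimum similarity for an edge.
#' @param similarity `"jaccard"` or `"overlap"` (overlap coefficient).
#' @return list with `nodes`, `edges` data.frames and `graph` (igraph).
#' @export
build_enrichment_map <- function(results, sets, universe, q_cut = 0.05,
                                 sim_cut = 0.25,
                                 similarity = c("jaccard", "overlap")) {
  similarity <- match.arg(similarity)
  if (!"q" %in% colnames(results)) stop("results must carry q values")
  sig <- results[results$q < q_cut, , drop = FALSE]
  members <- lapply(sets[sig$set], function(s) intersect(unique(s), universe))
  nodes <- data.frame(set = sig$set, q = sig$q,
                      size = vapply(members, length, 1L),
                      stringsAsFactors = FALSE, row.names = NULL)
  if ("nes" %in% colnames(sig)) nodes$nes <- sig$nes
  edges <- data.frame(from = character(0), to = character(0),
                      similarity = numeric(0), stringsAsFactors = FALSE)
  if (nrow(nodes) > 1) {
    pairs <- utils::combn(nodes$set, 2)
    sim <- apply(pairs, 2, function(pr) {
      a <- members[[pr[1]]]
      b <- members[[pr[2]]]
      inter <- length(intersect(a, b))
      denom <- switch(similarity,
                      jaccard = length(union(a, b)),
                      overlap = min(length(a), length(b)))
      if (denom == 0) 0 else inter / denom
    })
    keep <- sim >= sim_cut
    edges <- data.frame(from = pairs[1, keep], to = pairs[2, keep],
                        similarity = sim[keep], stringsAsFactors = FALSE)
  }
  graph <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = nodes)
  list(nodes = nodes, edges = edges, graph = graph)
}
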