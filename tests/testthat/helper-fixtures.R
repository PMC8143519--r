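# Shared fixture builders. All synthetic data is generated in code at test
# time; sizes are kept small so the whole suite runs quickly.

small_sim <- function(n_genes = 300, seed = 11, noise_sd = 0.25, ...) {
  cfg <- simulation_config(n_genes = n_genes, tissues = "soft_tissue",
                           noise_sd = noise_sd, seed = seed,
                           n_cell_types = 2, signature_size = 5, ...)
  sim <- simulate_counts(cfg)
  list(cfg = cfg, sim = sim)
}

normalized_expr <- function(sim) {
  normalize_expression(sim$counts, sim$gene_lengths, tmm_factors(sim$counts))
}

# deterministic composition-biased two-sample toy (10% of genes 8-fold up
# in sample B); used for the TMM reference comparison
tmm_toy <- function() {
  base <- 20L + (seq_len(300) * 37L) %% 211L
  toy <- cbind(A = base, B = base)
  toy[1:30, "B"] <- toy[1:30, "B"] * 8L
  rownames(toy) <- sprintf("g%03d", seq_len(300))
  toy
}

# brute-force running-sum enrichment score: literal walk down the list,
# independent of the package's cumulative-sum implementation
brute_force_es <- function(scores, set, p_exp = 1) {
  hit <- names(scores) %in% set
  nr <- sum(abs(scores[hit])^p_exp)
  n <- length(scores)
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      cur <- cur + if (nr > 0) abs(scores[i])^p_exp / nr else 1 / sum(hit)
    } else {
      cur <- cur - 1 / (n - sum(hit))
    }
    running[i] <- cur
  }
  hi <- max(running)
  lo <- min(running)
  if (abs(hi) >= abs(lo)) hi else lo
}

# exhaustive upper-tail hypergeometric probability by enumerating all draws
enumerate_hyper_p <- function(k, K, n, N) {
  i <- seq(0, min(K, n))
  probs <- choose(K, i) * choose(N - K, n - i) / choose(N, n)
  sum(probs[i >= k])
}
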