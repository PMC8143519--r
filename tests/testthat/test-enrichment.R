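test_that("signed log-p ranking follows the fold-change sign rule", {
  de <- data.frame(gene = c("up", "down", "flat"),
                   log2FC = c(1, -1, 0.5),
                   p = c(0.01, 0.01, 1))
  r <- rank_genes(de)
  expect_equal(r$score[r$gene == "up"], 2)
  expect_equal(r$score[r$gene == "down"], -2)
  expect_equal(r$score[r$gene == "flat"], 0)
  expect_equal(r$gene, c("up", "flat", "down"))  # descending score
  expect_warning(rank_genes(data.frame(gene = "a", log2FC = 1, p = 0)),
                 "clamped")
})

test_that("enrichment score matches hand-computed boundary cases", {
  ranked <- data.frame(gene = c("a", "b", "c", "d"),
                       score = c(3, 2, 1, 0.5))
  expect_equal(gsea_es(ranked, "a")$es, 1)
  expect_equal(gsea_es(ranked, "d")$es, -1)
  expect_equal(gsea_es(ranked, c("a", "b", "c", "d"))$es, 1)
  expect_equal(gsea_es(ranked, "d")$leading_edge, "d")
  expect_error(gsea_es(ranked, "zz"), "intersect")
})

test_that("enrichment score equals a brute-force running-sum oracle", {
  withr::local_seed(2024)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    scores <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    names(scores) <- sprintf("g%03d", sample(1000, n))
    ranked <- data.frame(gene = names(scores), score = unname(scores))
    k <- sample(seq_len(max(1, n - 1)), 1)
    set <- sample(names(scores), k)
    expect_equal(gsea_es(ranked, set)$es, brute_force_es(scores, set),
                 tolerance = 1e-12)
    # reversing the ranked list negates the score
    rev_ranked <- data.frame(gene = rev(names(scores)),
                             score = -rev(unname(scores)))
    expect_equal(gsea_es(rev_ranked, set)$es, -gsea_es(ranked, set)$es,
                 tolerance = 1e-12)
    expect_lte(abs(gsea_es(ranked, set)$es), 1)
  }
})

test_that("permutation p-values are calibrated for random sets", {
  withr::local_seed(31)
  n <- 400
  ranked <- data.frame(gene = sprintf("g%04d", 1:n),
                       score = sort(rnorm(n, sd = 2), decreasing = TRUE))
  sets <- lapply(1:200, function(i) sample(ranked$gene, 25))
  names(sets) <- sprintf("decoy_%03d", 1:200)
  res <- gsea_preranked(ranked, sets, n_perm = 500, seed = 99)
  frac05 <- mean(res$p < 0.05)
  expect_gte(frac05, 0.01)
  expect_lte(frac05, 0.10)
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # determinism
  res2 <- gsea_preranked(ranked, sets, n_perm = 500, seed = 99)
  expect_identical(res$q, res2$q)
  expect_true(all(sign(res$nes) == sign(res$es) | res$es == 0))
})

test_that("hypergeometric ORA is exact and BH-adjusted", {
  universe <- sprintf("g%02d", 1:10)
  sets <- list(s1 = universe[1:4])
  res <- ora_hypergeometric(universe[1:5], sets, universe)
  expect_equal(res$p, 6 / 252, tolerance = 1e-12)  # C(4,4)C(6,1)/C(10,5)

  # k = 0 gives p = 1
  res0 <- ora_hypergeometric(universe[5:6], list(s = universe[1:2]), universe)
  expect_equal(res0$p, 1)
  # query = universe saturates every set
  resU <- ora_hypergeometric(universe, sets, universe)
  expect_equal(resU$overlap, 4L)
  expect_equal(resU$p, 1)
})

test_that("ORA matches exhaustive enumeration over all small configurations", {
  for (N in c(6, 9, 12)) {
    universe <- sprintf("u%02d", seq_len(N))
    for (K in 1:(N - 1)) {
      for (n in 1:N) {
        for (k in 0:min(K, n)) {
          if (k > n || (n - k) > (N - K)) next
          query <- c(universe[seq_len(k)],
                     universe[K + seq_len(n - k)])
          sets <- list(s = universe[seq_len(K)])
          res <- ora_hypergeometric(query, sets, universe)
          expect_equal(res$p, enumerate_hyper_p(k, K, n, N),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("BH q-values are monotone in p and never smaller than p", {
  withr::local_seed(8)
  universe <- sprintf("g%03d", 1:200)
  sets <- lapply(1:30, function(i) sample(universe, 20))
  names(sets) <- sprintf("s%02d", 1:30)
  res <- ora_hypergeometric(sample(universe, 40), sets, universe)
  expect_true(all(res$q >= res$p - 1e-12))
  expect_true(all(diff(res$q) >= -1e-12))  # sorted by p
})

test_that("enrichment map connects sets by Jaccard similarity", {
  universe <- letters
  sets <- list(A = c("a", "b", "c", "d"), B = c("c", "d", "e", "f"),
               C = c("x", "y", "z"), D = c("x", "y", "z"))
  res <- data.frame(set = names(sets), q = c(0.01, 0.01, 0.01, 0.01))
  em <- build_enrichment_map(res, sets, universe, sim_cut = 0.25)
  expect_equal(nrow(em$nodes), 4)
  pair_ab <- em$edges$similarity[(em$edges$from == "A" & em$edges$to == "B") |
                                   (em$edges$from == "B" & em$edges$to == "A")]
  expect_equal(pair_ab, 2 / 6, tolerance = 1e-12)
  pair_cd <- em$edges$similarity[(em$edges$from == "C" & em$edges$to == "D") |
                                   (em$edges$from == "D" & em$edges$to == "C")]
  expect_equal(pair_cd, 1)
  expect_false(any(em$edges$from == em$edges$to))

  # disjoint significant sets -> nodes without edges
  res_dis <- data.frame(set = c("A", "C"), q = c(0.01, 0.01))
  em3 <- build_enrichment_map(res_dis, sets, universe)
  expect_equal(nrow(em3$nodes), 2)
  expect_equal(nrow(em3$edges), 0)

  # non-significant sets are excluded
  res_ns <- data.frame(set = names(sets), q = c(0.01, 0.5, 0.5, 0.5))
  em4 <- build_enrichment_map(res_ns, sets, universe)
  expect_equal(em4$nodes$set, "A")
  expect_equal(igraph::vcount(em4$graph), 1)
})
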