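make_two_group <- function(n_genes = 40, n_per = 3, seed = 17) {
  withr::local_seed(seed)
  samples <- data.frame(
    sample = sprintf("s%d", seq_len(2 * n_per)),
    tissue = "soft_tissue",
    timepoint_dpa = rep(c(0, 3), each = n_per),
    treatment = "control",
    replicate = rep(seq_len(n_per), 2)
  )
  expr <- matrix(rnorm(n_genes * 2 * n_per), n_genes,
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                 samples$sample))
  list(expr = expr, samples = samples)
}

test_that("OLS coefficients are group means with the right residual df", {
  x <- small_sim(n_genes = 30, seed = 51)
  expr <- normalized_expr(x$sim)
  design <- build_design(x$sim$samples)
  expect_equal(colnames(design$design),
               c("t0", "t3_control", "t3_inhibitor", "t8_control",
                 "t8_inhibitor"))
  fit <- fit_linear_models(expr, x$sim$samples, design)
  expect_equal(fit$df_residual, 5)  # 10 samples - 5 groups

  # hand check: one group's coefficient is its replicate mean; residual
  # contribution of values {1, 3} in a 2-replicate group is 2
  g3c <- x$sim$samples$sample[x$sim$samples$timepoint_dpa == 3 &
                                x$sim$samples$treatment == "control"]
  e2 <- rbind(expr, g_test = 0)
  e2["g_test", g3c] <- c(1, 3)
  fit2 <- fit_linear_models(e2, x$sim$samples, design)
  expect_equal(unname(fit2$coefficients["g_test", "t3_control"]), 2)
  expect_equal(unname(fit2$sigma2["g_test"]) * fit2$df_residual, 2)

  # constant gene: all coefficients equal, zero residual variance
  e2["g_test", ] <- 4
  fit3 <- fit_linear_models(e2, x$sim$samples, design)
  expect_equal(unname(fit3$coefficients["g_test", ]), rep(4, 5))
  expect_equal(unname(fit3$sigma2["g_test"]), 0)

  # duplicated coefficient column -> rank error
  bad <- design
  bad$design <- cbind(bad$design, dup = bad$design[, 1])
  expect_error(fit_linear_models(expr, x$sim$samples, bad), "rank deficient")
})

test_that("variance moderation recovers known hyperparameters", {
  withr::local_seed(42)
  d0_true <- 4
  s0_true <- 2
  d <- 5
  s2 <- s0_true * d0_true / rchisq(5000, d0_true) * rchisq(5000, d) / d
  # scaled F draw: s2 ~ s0^2 * F(d, d0); moment-matching should recover
  mod <- moderate_variances(s2, d)
  expect_lt(abs(mod$d0 - d0_true) / d0_true, 0.25)
  expect_lt(abs(mod$s0_2 - s0_true) / s0_true, 0.10)
  expect_true(all(
    (mod$sigma2_post >= pmin(s2, mod$s0_2) - 1e-12) &
      (mod$sigma2_post <= pmax(s2, mod$s0_2) + 1e-12)
  ))

  # equal variances -> infinite prior df, full shrinkage to the common value
  mod_eq <- moderate_variances(rep(1.7, 100), 5)
  expect_true(is.infinite(mod_eq$d0))
  expect_equal(mod_eq$sigma2_post, rep(mod_eq$s0_2, 100))

  # forced d0 = 0 leaves variances untouched
  mod0 <- moderate_variances(s2, d, force_d0 = 0)
  expect_identical(mod0$sigma2_post, s2)
})

test_that("moderation agrees with the established empirical-Bayes fit", {
  skip_if_not_installed("limma")
  withr::local_seed(7)
  s2 <- 2 * 4 / rchisq(2000, 4) * rchisq(2000, 5) / 5
  mine <- moderate_variances(s2, 5)
  ref <- limma::squeezeVar(s2, df = 5)
  expect_equal(mine$d0, ref$df.prior, tolerance = 1e-6)
  expect_equal(mine$s0_2, ref$var.prior, tolerance = 1e-6)
  expect_equal(mine$sigma2_post, ref$var.post, tolerance = 1e-8)
})

test_that("unmoderated contrast t equals the classical pooled t-test", {
  x <- make_two_group()
  fit <- fit_linear_models(x$expr, x$samples)
  mod0 <- moderate_variances(fit$sigma2, fit$df_residual, force_d0 = 0)
  res <- run_contrast(fit, c(t3_control = 1, t0 = -1), mod0, name = "3v0")
  for (g in rownames(x$expr)[1:10]) {
    tt <- t.test(x$expr[g, x$samples$timepoint_dpa == 3],
                 x$expr[g, x$samples$timepoint_dpa == 0], var.equal = TRUE)
    expect_equal(res$t[res$gene == g], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[res$gene == g], tt$p.value, tolerance = 1e-10)
  }
})

test_that("contrast edge cases behave as specified", {
  x <- make_two_group(n_genes = 20)
  fit <- fit_linear_models(x$expr, x$samples)
  expect_error(run_contrast(fit, c(0, 0)), "all zero")
  # beta = 0 -> t = 0, p = 1
  e0 <- x$expr
  e0[1, ] <- 5
  fit0 <- fit_linear_models(e0, x$samples)
  mod <- moderate_variances(fit0$sigma2, fit0$df_residual)
  r <- run_contrast(fit0, c(1, -1), mod)
  expect_equal(r$t[1], 0)
  expect_equal(r$p[1], 1)
  # monotonicity: scaling a gene's effect up increases |t|
  e1 <- x$expr
  e1[2, x$samples$timepoint_dpa == 3] <- e1[2, x$samples$timepoint_dpa == 3] + 1
  e2 <- e1
  e2[2, x$samples$timepoint_dpa == 3] <- e2[2, x$samples$timepoint_dpa == 3] + 2
  f1 <- fit_linear_models(e1, x$samples)
  f2 <- fit_linear_models(e2, x$samples)
  shared <- moderate_variances(f1$sigma2, f1$df_residual, force_d0 = 0)
  t1 <- run_contrast(f1, c(-1, 1), shared)$t[2]
  t2 <- run_contrast(f2, c(-1, 1), shared)$t[2]
  expect_gt(abs(t2), abs(t1))
})

test_that("dynamic-gene filter takes the union over all six comparisons", {
  mk <- function(p) data.frame(gene = c("gA", "gB"), log2FC = 1,
                               t = 1, p = p)
  nm <- c("3v0_ctrl", "8v0_ctrl", "8v3_ctrl", "3v0_inh", "8v0_inh", "8v3_inh")
  de <- setNames(list(mk(c(0.2, 0.5)), mk(c(0.9, 0.9)), mk(c(0.04, 0.9)),
                      mk(c(0.5, 0.9)), mk(c(0.6, 0.9)), mk(c(0.7, 0.9))), nm)
  expect_identical(select_dynamic_genes(de), "gA")
  expect_error(select_dynamic_genes(de[-2]), "8v0_ctrl")
})

test_that("null simulated data rejects near the nominal rate", {
  cfg <- simulation_config(n_genes = 5000, tissues = "soft_tissue",
                           amplitude = 0, frac_shifted = 0, n_cell_types = 0,
                           seed = 77)
  sim <- simulate_counts(cfg)
  expr <- normalized_expr(sim)
  de <- run_de(expr, sim$samples)
  rate <- mean(de$results[["3v0_ctrl"]]$p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
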