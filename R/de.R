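#' Cell-means design matrix for one tissue arm
#'
#' Builds an indicator (group-mean) design over the condition groups of a
#' single tissue: the shared homeostatic baseline forms one group and every
#' later (timepoint, treatment) combination its own group, e.g.
#' `t0, t3_control, t8_control, t3_inhibitor, t8_inhibitor`.
#'
#' @param samples sample table for one tissue (see [read_sample_table()]).
#' @return list with `design` (samples x groups indicator matrix), `groups`
#'   (factor aligned to rows) and `group_names`.
#' @export
build_design <- function(samples) {
  if (length(unique(samples$tissue)) != 1) {
    stop("build_design expects samples from a single tissue; got: ",
         paste(unique(samples$tissue), collapse = ", "))
  }
  tp <- samples$timepoint_dpa
  base_tp <- min(tp)
  grp <- ifelse(tp == base_tp, sprintf("t%s", base_tp),
                sprintf("t%s_%s", tp, samples$treatment))
  ord <- order(match(tp, sort(unique(tp))), samples$treatment)
  levels <- unique(grp[ord])
  groups <- factor(grp, levels = levels)
  if (any(table(groups) == 0)) stop("design has an empty condition group")
  design <- stats::model.matrix(~ 0 + groups)
  colnames(design) <- levels
  rownames(design) <- samples$sample
  if (qr(design)$rank < ncol(design)) stop("design matrix is rank deficient")
  list(design = design, groups = groups, group_names = levels)
}

#' Gene-wise ordinary least squares over a design matrix
#'
#' Fits every gene's expression profile against the same design by OLS.
#' Under indicator coding the coefficients are condition-group means.
#'
#' @param expr expression matrix (genes x samples) on the log2 scale.
#' @param samples sample table whose `sample` column matches `expr` columns.
#' @param design optional design list from [build_design()]; built from
#'   `samples` when omitted.
#' @return list of class `"gene_fit"` with `coefficients` (genes x
#'   coefficients), `sigma2` (residual variances), `df_residual`,
#'   `design`, and `xtx_inv`.
#' @export
fit_linear_models <- function(expr, samples, design = NULL) {
  design <- design %||% build_design(samples)
  X <- design$design
  missing <- setdiff(rownames(X), colnames(expr))
  if (length(missing)) {
    stop("samples absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  Y <- expr[, rownames(X), drop = FALSE]
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  xtx_inv <- solve(crossprod(X))
  B <- Y %*% X %*% xtx_inv          # genes x coefficients
  fitted <- B %*% t(X)
  res <- Y - fitted
  df <- nrow(X) - ncol(X)
  if (df < 1) stop("no residual degrees of freedom")
  sigma2 <- rowSums(res^2) / df
  structure(list(
    coefficients = B, sigma2 = sigma2, df_residual = df,
    design = X, xtx_inv = xtx_inv, coef_names = colnames(X)
  ), class = "gene_fit")
}

## Newton inversion of the trigamma function, used by the moment-matching
## hyperparameter fit.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0^2` of
#' a scaled inverse chi-square prior by moment matching on `log(s^2)`, then
#' shrinks every gene's residual variance towards the prior:
#' `s_tilde^2 = (d0 * s0^2 + d * s^2) / (d0 + d)`. When the gene-wise
#' variances carry no excess spread beyond chi-square sampling noise,
#' `d0 = Inf` and all posterior variances equal `s0^2`.
#'
#' @param sigma2 gene-wise residual variances.
#' @param df residual degrees of freedom (scalar or per gene).
#' @param force_d0 optional fixed prior df (e.g. `0` for no moderation,
#'   `Inf` for full pooling), bypassing estimation.
#' @return list with `d0`, `s0_2`, and `sigma2_post` (posterior variances).
#' @export
moderate_variances <- function(sigma2, df, force_d0 = NULL) {
  df <- rep_len(df, length(sigma2))
  ok <- df > 0 & is.finite(sigma2)
  if (sum(ok) < 10 && is.null(force_d0)) {
    stop("need >= 10 genes with positive residual df to fit the prior")
  }
  if (!is.null(force_d0)) {
    d0 <- force_d0
    s0_2 <- if (is.finite(d0) && d0 == 0) NA_real_ else mean(sigma2[ok])
  } else if (all(sigma2[ok] == 0)) {
    warning("all residual variances are zero; prior df set to Inf")
    d0 <- Inf
    s0_2 <- 0
  } else {
    s2 <- pmax(sigma2[ok], 1e-300)
    z <- log(s2)
    e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
    emean <- mean(e)
    evar <- sum((e - emean)^2) / (sum(ok) - 1) - mean(trigamma(df[ok] / 2))
    if (evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_2 <- exp(emean)
    }
  }
  sigma2_post <- if (is.infinite(d0)) {
    rep(s0_2, length(sigma2))
  } else if (d0 == 0) {
    sigma2
  } else {
    (d0 * s0_2 + df * sigma2) / (d0 + df)
  }
  list(d0 = d0, s0_2 = s0_2, sigma2_post = sigma2_post)
}

#' Moderated t-test of a single contrast
#'
#' Tests `c' beta = 0` per gene with the moderated statistic
#' `t = c'beta / (s_tilde * sqrt(c' (X'X)^-1 c))` on `d0 + d` degrees of
#' freedom (two-sided).
#'
#' @param fit a [fit_linear_models()] result.
#' @param contrast numeric contrast vector over the fit's coefficients
#'   (optionally named by coefficient).
#' @param moderation a [moderate_variances()] result; computed from the fit
#'   when omitted.
#' @param name contrast label carried into the output.
#' @return data.frame with columns `gene`, `contrast`, `log2FC`, `t`, `p`.
#' @export
run_contrast <- function(fit, contrast, moderation = NULL, name = "contrast") {
  p_coef <- ncol(fit$coefficients)
  if (!is.null(names(contrast))) {
    cv <- rep(0, p_coef)
    idx <- match(names(contrast), fit$coef_names)
    if (any(is.na(idx))) {
      stop("unknown coefficient(s): ",
           paste(names(contrast)[is.na(idx)], collapse = ", "))
    }
    cv[idx] <- contrast
  } else {
    cv <- as.numeric(contrast)
  }
  if (length(cv) != p_coef) stop("contrast length does not match coefficients")
  if (all(cv == 0)) stop("contrast vector is all zero")
  moderation <- moderation %||%
    moderate_variances(fit$sigma2, fit$df_residual)
  scale2 <- drop(t(cv) %*% fit$xtx_inv %*% cv)
  if (scale2 <= 0) stop("contrast is not estimable under this design")
  est <- drop(fit$coefficients %*% cv)
  se <- sqrt(moderation$sigma2_post * scale2)
  tstat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, sign(est) * Inf))
  df_total <- moderation$d0 + fit$df_residual
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)
  pval[tstat == 0] <- 1
  data.frame(gene = rownames(fit$coefficients), contrast = name,
             log2FC = est, t = tstat, p = pval,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' The six pairwise stage comparisons of one tissue arm
#'
#' Contrast vectors for 3 vs 0, 8 vs 0 and 8 vs 3 dpa under each treatment
#' arm, against the group names of [build_design()].
#'
#' @param group_names coefficient names, e.g.
#'   `c("t0", "t3_control", "t8_control", "t3_inhibitor", "t8_inhibitor")`.
#' @param timepoints the three ordered timepoints (defaults to 0, 3, 8).
#' @param treatments the two treatment labels.
#' @return named list of named contrast vectors.
#' @export
default_contrasts <- function(group_names, timepoints = c(0, 3, 8),
                              treatments = c("control", "inhibitor")) {
  t0 <- sprintf("t%s", timepoints[1])
  short <- c(control = "ctrl", inhibitor = "inh")
  out <- list()
  for (trt in treatments) {
    g3 <- sprintf("t%s_%s", timepoints[2], trt)
    g8 <- sprintf("t%s_%s", timepoints[3], trt)
    tag <- if (trt %in% names(short)) short[[trt]] else trt
    out[[sprintf("%sv%s_%s", timepoints[2], timepoints[1], tag)]] <-
      stats::setNames(c(1, -1), c(g3, t0))
    out[[sprintf("%sv%s_%s", timepoints[3], timepoints[1], tag)]] <-
      stats::setNames(c(1, -1), c(g8, t0))
    out[[sprintf("%sv%s_%s", timepoints[3], timepoints[2], tag)]] <-
      stats::setNames(c(1, -1), c(g8, g3))
  }
  missing <- setdiff(unique(unlist(lapply(out, names))), group_names)
  if (length(missing)) {
    stop("design lacks groups required by the stage contrasts: ",
         paste(missing, collapse = ", "))
  }
  out
}

#' Run the full moderated-t analysis for one tissue
#'
#' Convenience driver: fits the cell-means models, moderates variances,
#' and evaluates all six stage comparisons.
#'
#' @param expr expression matrix (genes x samples).
#' @param samples single-tissue sample table.
#' @param force_d0 optional fixed prior df passed to
#'   [moderate_variances()].
#' @return list with `fit`, `moderation` and `results` (one data.frame per
#'   contrast).
#' @export
run_de <- function(expr, samples, force_d0 = NULL) {
  design <- build_design(samples)
  fit <- fit_linear_models(expr, samples, design)
  moderation <- moderate_variances(fit$sigma2, fit$df_residual,
                                   force_d0 = force_d0)
  tps <- sort(unique(samples$timepoint_dpa))
  trts <- unique(c(intersect(c("control", "inhibitor"),
                             unique(samples$treatment)),
                   unique(samples$treatment)))
  contrasts <- default_contrasts(design$group_names, timepoints = tps,
                                 treatments = trts)
  results <- lapply(names(contrasts), function(nm) {
    run_contrast(fit, contrasts[[nm]], moderation, name = nm)
  })
  names(results) <- names(contrasts)
  list(fit = fit, moderation = moderation, results = results)
}

#' Select dynamic genes by the pairwise-comparison filter
#'
#' A gene is "dynamic" if its unadjusted p-value falls below `p_cut` in at
#' least one of the six stage comparisons (3v0, 8v0, 8v3 under each
#' treatment arm). No multiplicity adjustment is applied at this filtering
#' step.
#'
#' @param de_results named list of contrast data.frames (from [run_de()]'s
#'   `results`), containing all six comparisons.
#' @param p_cut unadjusted p-value threshold (default 0.05).
#' @param required contrast names that must be present.
#' @return character vector of gene identifiers, sorted.
#' @export
select_dynamic_genes <- function(de_results, p_cut = 0.05,
                                 required = c("3v0_ctrl", "8v0_ctrl",
                                              "8v3_ctrl", "3v0_inh",
                                              "8v0_inh", "8v3_inh")) {
  missing <- setdiff(required, names(de_results))
  if (length(missing)) {
    stop("missing comparison(s): ", paste(missing, collapse = ", "))
  }
  hits <- lapply(de_results[required], function(df) df$gene[df$p < p_cut])
  sort(unique(unlist(hits)))
}
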