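#' Per-gene linear age regression
#'
#' Fits, by ordinary least squares, the model
#' \deqn{Y_i = \mu + Age_i\alpha + Sex_i\beta + BMI_i\gamma +
#'   \sum_k PC_{ki}\delta_k + \epsilon_i}
#' for a single gene and reports the age slope \eqn{\alpha} with its
#' standard error, t statistic and two-sided P-value. A gene is
#' age-associated when \eqn{\alpha} deviates significantly from 0;
#' up-regulated with age if \eqn{\alpha > 0}, down-regulated if
#' \eqn{\alpha < 0}.
#'
#' @param y numeric expression vector (one gene).
#' @param age ages in years.
#' @param sex binary sex (0/1 numeric, or "male"/"female" character).
#' @param bmi body mass index vector, or `NULL` to omit.
#' @param factors samples x N matrix of kept hidden-factor scores, or `NULL`.
#' @return A list of class `AgeModelFit` with the coefficient set
#'   (`alpha`, `beta`, `gamma`, `delta`, `mu`), `alpha_se`, `alpha_t`,
#'   `alpha_p` and residual degrees of freedom.
#' @export
fit_age_model <- function(y, age, sex = NULL, bmi = NULL, factors = NULL) {
  X <- age_design(length(y), age, sex, bmi, factors)
  fit <- ols_multi(matrix(y, nrow = 1L), X)
  delta <- if (!is.null(factors) && ncol(factors) > 0L) {
    fit$coef[1L, grep("^factor", colnames(X)), drop = TRUE]
  } else numeric(0)
  structure(list(
    mu = unname(fit$coef[1L, "intercept"]),
    alpha = unname(fit$coef[1L, "age"]),
    beta = if ("sex" %in% colnames(X)) unname(fit$coef[1L, "sex"]) else NA_real_,
    gamma = if ("bmi" %in% colnames(X)) unname(fit$coef[1L, "bmi"]) else NA_real_,
    delta = delta,
    alpha_se = unname(fit$se[1L, "age"]),
    alpha_t = unname(fit$tstat[1L, "age"]),
    alpha_p = unname(fit$pvalue[1L, "age"]),
    df = fit$df,
    residuals = drop(fit$residuals)
  ), class = "AgeModelFit")
}

#' @export
print.AgeModelFit <- function(x, ...) {
  cat(sprintf("AgeModelFit: alpha = %.4g (se %.3g), t = %.3g, P = %.3g, df = %d\n",
              x$alpha, x$alpha_se, x$alpha_t, x$alpha_p, x$df))
  invisible(x)
}

age_design <- function(n, age, sex, bmi, factors) {
  stopifnot(length(age) == n)
  cols <- list(intercept = rep(1, n), age = as.numeric(age))
  if (!is.null(sex)) {
    cols$sex <- if (is.character(sex)) sex_to_numeric(sex) else as.numeric(sex)
  }
  if (!is.null(bmi)) cols$bmi <- as.numeric(bmi)
  X <- do.call(cbind, cols)
  if (!is.null(factors) && ncol(factors) > 0L) {
    fn <- colnames(factors)
    if (is.null(fn)) fn <- paste0("factor", seq_len(ncol(factors)))
    X <- cbind(X, factors)
    colnames(X) <- c(names(cols), fn)
  }
  X
}

#' Age regression across all genes of a matrix
#'
#' Runs the per-gene age model for every row of an expression matrix on a
#' shared design (a single QR factorization), which is algebraically
#' identical to gene-by-gene fits.
#'
#' @param expr an [expression_matrix()] (typically state `"residual"` when
#'   factors were already removed, or `"lognorm"` with `factors` supplied).
#' @param covs covariate data frame; `sex`/`bmi` are taken from it unless
#'   `use_covariates = FALSE` (appropriate for residual input, where they
#'   are already removed).
#' @param factors kept-factor score matrix or `NULL`.
#' @param use_covariates include sex and BMI in the design (default TRUE).
#' @return A data frame with one row per gene: `gene_id`, `estimate`
#'   (alpha, expression units per year), `stderr`, `tstat`, `pvalue`.
#' @export
age_scan <- function(expr, covs, factors = NULL, use_covariates = TRUE) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  stopifnot(all(expr$sample_ids == covs$sample_id))
  n <- length(expr$sample_ids)
  X <- age_design(n, covs$age,
                  sex = if (use_covariates) covs$sex else NULL,
                  bmi = if (use_covariates) covs$bmi else NULL,
                  factors = factors)
  fit <- ols_multi(expr$values, X)
  data.frame(
    gene_id = expr$gene_ids,
    estimate = fit$coef[, "age"],
    stderr = fit$se[, "age"],
    tstat = fit$tstat[, "age"],
    pvalue = fit$pvalue[, "age"],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Call age-associated genes at Benjamini-Hochberg FDR tiers
#'
#' Applies the BH step-up adjustment to the per-gene P-values and tallies
#' up/down/total calls at each requested FDR level; direction follows the
#' sign of the age slope.
#'
#' @param fits data frame from [age_scan()] (or a list of `AgeModelFit`
#'   objects with gene ids as names).
#' @param fdr_levels FDR tiers to tally (default 1%, 5%, 10%).
#' @return An association table: `unit_id`, `estimate`, `stderr`, `tstat`,
#'   `pvalue`, `adjusted`, `direction` (at the strictest level the gene
#'   passes, `"none"` otherwise), with a `counts` attribute — a data frame
#'   of up/down/total per FDR level.
#' @export
call_age_genes <- function(fits, fdr_levels = c(0.01, 0.05, 0.10)) {
  if (is.list(fits) && !is.data.frame(fits)) {
    fits <- data.frame(
      gene_id = names(fits),
      estimate = vapply(fits, function(f) f$alpha, 0),
      stderr = vapply(fits, function(f) f$alpha_se, 0),
      tstat = vapply(fits, function(f) f$alpha_t, 0),
      pvalue = vapply(fits, function(f) f$alpha_p, 0),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(fits) == 0L) stop("empty fit list")
  adjusted <- stats::p.adjust(fits$pvalue, method = "BH")
  sig_any <- adjusted <= max(fdr_levels)
  direction <- ifelse(sig_any & fits$estimate > 0, "up",
                      ifelse(sig_any & fits$estimate < 0, "down", "none"))
  counts <- do.call(rbind, lapply(sort(fdr_levels), function(q) {
    sel <- adjusted <= q
    data.frame(fdr = q,
               up = sum(sel & fits$estimate > 0),
               down = sum(sel & fits$estimate < 0),
               total = sum(sel))
  }))
  out <- data.frame(unit_id = fits$gene_id, estimate = fits$estimate,
                    stderr = fits$stderr, tstat = fits$tstat,
                    pvalue = fits$pvalue, adjusted = adjusted,
                    direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "counts") <- counts
  out
}

#' Subsampling robustness of age-gene counts
#'
#' Repeatedly subsamples the cohort without replacement to a target size,
#' reruns the confounder correction and age-gene calling on each draw, and
#' reports per-replicate counts at each FDR tier. This probes whether
#' regional differences in age-gene counts persist when sample sizes are
#' equalized (the smallest study region has 54 donors).
#'
#' @param expr an [expression_matrix()] with `state = "lognorm"`.
#' @param covs covariate data frame.
#' @param n_target subsample size (must not exceed the cohort size).
#' @param reps number of replicates (default 20).
#' @param seed integer seed; each replicate draws deterministically from it.
#' @param K factors for the refitted correction (default 15, clamped to the
#'   rank bound).
#' @param fdr_levels FDR tiers to tally.
#' @param refit_factors refit hidden factors inside each subsample (default
#'   TRUE) or reuse full-data kept factors subsetted to the draw.
#' @return A data frame of counts per replicate and FDR level, with a
#'   `mean_counts` attribute.
#' @export
subsample_robustness <- function(expr, covs, n_target, reps = 20L, seed = 1L,
                                 K = 15, fdr_levels = c(0.01, 0.05, 0.10),
                                 refit_factors = TRUE) {
  n <- length(expr$sample_ids)
  if (n_target > n) stop("n_target exceeds the number of samples")
  full_model <- if (!refit_factors) {
    m <- fit_hidden_factors(expr, covs, K = clamp_K(K, expr, covs))
    filter_age_correlated_factors(m, covs$age)
  } else NULL
  rows <- list()
  for (r in seq_len(reps)) {
    idx <- with_seed(seed + r - 1L,
                     sort(sample.int(n, n_target, replace = FALSE)))
    sub_expr <- expression_matrix(expr$values[, idx, drop = FALSE],
                                  state = expr$state)
    sub_covs <- covs[idx, , drop = FALSE]
    if (refit_factors) {
      model <- fit_hidden_factors(sub_expr, sub_covs,
                                  K = clamp_K(K, sub_expr, sub_covs))
      model <- filter_age_correlated_factors(model, sub_covs$age)
      scores <- kept_factor_scores(model)
    } else {
      full_kept <- kept_factor_scores(full_model)
      scores <- full_kept[idx, , drop = FALSE]
    }
    calls <- call_age_genes(age_scan(sub_expr, sub_covs, factors = scores),
                            fdr_levels = fdr_levels)
    cnt <- attr(calls, "counts")
    cnt$rep <- r
    rows[[r]] <- cnt
  }
  out <- do.call(rbind, rows)
  attr(out, "mean_counts") <- stats::aggregate(total ~ fdr, out, mean)
  out
}

clamp_K <- function(K, expr, covs) {
  C <- ncol(covariate_design(covs, include_age = TRUE))
  max(0L, min(K, min(length(expr$gene_ids), length(expr$sample_ids)) - C - 1L))
}

#' Cross-region concordance of age responsiveness
#'
#' Measures, for every pair of regions, the Spearman rank correlation
#' between the per-gene age-test P-values (a gene's P-value being its
#' responsiveness to aging), on the intersection of gene ids; regions are
#' then ordered by average-linkage hierarchical clustering of 1 - SCC for
#' display.
#'
#' @param pvalue_tables named list, one element per region, each a named
#'   numeric vector of per-gene P-values (names = gene ids).
#' @return A symmetric region x region matrix of Spearman coefficients with
#'   unit diagonal; attributes `order` (display ordering) and `hclust`.
#' @export
cross_region_concordance <- function(pvalue_tables) {
  if (length(pvalue_tables) < 2L) stop("need at least 2 regions")
  common <- Reduce(intersect, lapply(pvalue_tables, names))
  if (length(common) < 10L) {
    stop("fewer than 10 genes shared across regions")
  }
  P <- vapply(pvalue_tables, function(p) p[common], numeric(length(common)))
  scc <- stats::cor(P, method = "spearman")
  diag(scc) <- 1
  hc <- stats::hclust(stats::as.dist(1 - scc), method = "average")
  attr(scc, "order") <- hc$order
  attr(scc, "hclust") <- hc
  scc
}
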