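#' Phenotype-factor scores for one gene set
#'
#' Summarizes the confounder-corrected residual expression of a gene set by
#' latent factors ("phenotype factors"): the factor engine is applied to
#' the gene-subset matrix with an intercept-only design (global structure
#' and known covariates were already removed upstream). The scores are
#' concise summaries of the set's common expression variation and are
#' treated as derived phenotypes.
#'
#' @param resid an [expression_matrix()] with `state = "residual"`.
#' @param geneset character vector of gene ids; ids absent from the matrix
#'   are dropped with a message.
#' @param K number of factors; capped at `min(K, set size - 1)`
#'   (default 5).
#' @return samples x K matrix of unit-variance factor scores, or `NULL`
#'   (with a message) when fewer than 2 set genes are present.
#' @export
pathway_factor_scores <- function(resid, geneset, K = 5) {
  stopifnot(inherits(resid, "ExpressionMatrix"))
  present <- intersect(geneset, resid$gene_ids)
  dropped <- setdiff(geneset, present)
  if (length(dropped)) {
    message(length(dropped), " gene(s) from the set absent from the matrix")
  }
  if (length(present) < 2L) {
    message("set skipped: fewer than 2 genes present")
    return(NULL)
  }
  K <- min(K, length(present) - 1L,
           length(resid$sample_ids) - 2L)
  sub <- expression_matrix(resid$values[present, , drop = FALSE],
                           state = resid$state)
  model <- fit_hidden_factors(sub, covs = NULL, K = K)
  model$scores
}

#' Test phenotype factors of a gene set against age
#'
#' Each factor is tested by the Pearson correlation test against donor age;
#' the set's P-value is the minimum over its factors, and the Bonferroni
#' adjustment multiplies by the total number of sets tested times the
#' number of factors per set (conservative; preserves family-wise error
#' across both sets and factors). A set is significant when the adjusted
#' value is below 0.05.
#'
#' @param scores samples x K factor-score matrix from
#'   [pathway_factor_scores()].
#' @param age ages in years.
#' @param n_sets_tested total number of gene sets in the scan (the
#'   Bonferroni family size).
#' @param unit_id label for the output row.
#' @return A one-row association data frame (`unit_id`, `estimate` = the
#'   best factor's correlation, `pvalue`, `adjusted`, `direction`,
#'   `factor` = index of the best factor).
#' @export
test_pathway_age <- function(scores, age, n_sets_tested, unit_id = "set") {
  if (n_sets_tested < 1L) stop("n_sets_tested must be >= 1")
  K <- ncol(scores)
  res <- lapply(seq_len(K), function(k) {
    s <- scores[, k]
    if (stats::sd(s) == 0) return(NULL)      # constant factor: skip
    ct <- stats::cor.test(s, age, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, k = k)
  })
  res <- Filter(Negate(is.null), res)
  if (!length(res)) stop("all factors constant; nothing to test")
  best <- res[[which.min(vapply(res, `[[`, 0, "p"))]]
  adjusted <- min(1, best$p * n_sets_tested * K)
  data.frame(
    unit_id = unit_id,
    estimate = best$r,
    pvalue = best$p,
    adjusted = adjusted,
    significant = adjusted < 0.05,
    direction = ifelse(best$r > 0, "up", ifelse(best$r < 0, "down", "none")),
    factor = best$k,
    stringsAsFactors = FALSE
  )
}

#' Scan a gene-set collection for age-associated pathway factors
#'
#' @param resid residual [expression_matrix()].
#' @param sets a [gene_set_collection()].
#' @param age ages in years (same sample order as `resid`).
#' @param K factors per set before the size cap (default 5).
#' @return Association data frame, one row per testable set, sorted by
#'   P-value; skipped sets are recorded in attribute `skipped`.
#' @export
pathway_scan <- function(resid, sets, age, K = 5) {
  n_sets <- length(sets)
  rows <- list()
  skipped <- character(0)
  for (id in names(sets)) {
    scores <- suppressMessages(pathway_factor_scores(resid, sets[[id]], K = K))
    if (is.null(scores)) {
      skipped <- c(skipped, id)
      next
    }
    rows[[id]] <- test_pathway_age(scores, age, n_sets_tested = n_sets,
                                   unit_id = id)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit_id = character(0), estimate = numeric(0),
               pvalue = numeric(0), adjusted = numeric(0),
               significant = logical(0), direction = character(0),
               factor = integer(0))
  out <- out[order(out$pvalue), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "n_sets_tested") <- n_sets
  out
}
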