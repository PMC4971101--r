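#' Minor allele frequency from dosage codes
#'
#' Computes the non-reference allele frequency `f = sum(codes) / (2 n)` over
#' non-missing diploid calls and folds it to `min(f, 1 - f)`.
#'
#' @param codes genotype dosage vector in `{0, 1, 2, NA}`.
#' @return MAF in `[0, 0.5]`.
#' @export
compute_maf <- function(codes) {
  codes <- codes[!is.na(codes)]
  if (!length(codes)) stop("all genotype codes missing; MAF undefined")
  f <- sum(codes) / (2 * length(codes))
  min(f, 1 - f)
}

#' Genotype-by-age interaction model for one SNP-gene pair
#'
#' Extends the per-gene age regression with an additive genotype dosage
#' term and a genotype x age interaction; the reported P-value is the
#' two-sided t-test on the interaction coefficient, which captures
#' age-dependent genetic effects on expression. Samples with missing
#' genotype are dropped pairwise (complete-case per SNP).
#'
#' @param y expression vector.
#' @param g genotype dosage codes in `{0, 1, 2, NA}`.
#' @param age ages in years.
#' @param covs optional samples x C numeric covariate matrix (sex, BMI,
#'   kept factors), aligned with `y`.
#' @return A one-row data frame (`estimate`, `stderr`, `tstat`, `pvalue`
#'   for the interaction term, plus `g_main` and `n_used`), or `NULL` with
#'   a message when the genotype is monomorphic after the missing-drop.
#' @export
fit_interaction_model <- function(y, g, age, covs = NULL) {
  keep <- !is.na(g)
  y <- y[keep]; g <- g[keep]; age <- age[keep]
  if (!is.null(covs)) covs <- covs[keep, , drop = FALSE]
  if (length(unique(g)) < 2L) {
    message("monomorphic genotype after missing-drop; pair skipped")
    return(NULL)
  }
  n <- length(y)
  X <- cbind(intercept = rep(1, n), age = age)
  if (!is.null(covs)) X <- cbind(X, covs)
  X <- cbind(X, g = g, g_age = g * age)
  p <- ncol(X)
  if (n < p + 2L) stop("too few complete samples (", n, ") for ", p,
                       " parameters")
  fit <- ols_multi(matrix(y, nrow = 1L), X)
  data.frame(
    estimate = fit$coef[1L, "g_age"],
    stderr = fit$se[1L, "g_age"],
    tstat = fit$tstat[1L, "g_age"],
    pvalue = fit$pvalue[1L, "g_age"],
    g_main = fit$coef[1L, "g"],
    n_used = n,
    stringsAsFactors = FALSE
  )
}

#' Genome-wide genotype-by-age interaction scan
#'
#' Draws a seeded random subset of genes, restricts SNPs to those passing
#' the MAF filter (study threshold: MAF > 15%), forms SNP-gene pairs either
#' from an explicit pair list or from a cis window around each gene
#' (default +/- 1 Mb), fits the interaction model per pair and reports
#' pairs below the nominal reporting threshold (default P < 1e-5). No
#' multiple-testing correction is applied; the output is flagged
#' `"nominal"`.
#'
#' @param expr an [expression_matrix()] (residual or lognorm).
#' @param genotypes a [genotype_matrix()] covering the same samples.
#' @param covs covariate data frame; sex and BMI enter the model unless
#'   `use_covariates = FALSE`.
#' @param n_genes number of genes to draw (default 2000, capped at the
#'   number available).
#' @param maf_min MAF inclusion threshold, exclusive (default 0.15).
#' @param p_report nominal reporting threshold (default 1e-5).
#' @param seed integer seed for the gene draw.
#' @param gene_pos optional data frame `gene_id`, `chrom`, `pos` used for
#'   cis pairing.
#' @param cis_window half-width of the cis window in bp (default 1e6).
#' @param pairs optional explicit data frame `snp_id`, `gene_id`; overrides
#'   cis pairing.
#' @param factors optional kept-factor score matrix added to the design.
#' @param use_covariates include sex and BMI (default TRUE).
#' @return Association data frame of reported pairs (columns `unit_id`
#'   (`snp:gene`), `snp_id`, `gene_id`, `estimate`, `stderr`, `tstat`,
#'   `pvalue`, `flag = "nominal"`), sorted by P; attributes `n_pairs_tested`,
#'   `genes_used`, `all_pvalues`.
#' @export
interaction_scan <- function(expr, genotypes, covs, n_genes = 2000L,
                             maf_min = 0.15, p_report = 1e-5, seed = 1L,
                             gene_pos = NULL, cis_window = 1e6,
                             pairs = NULL, factors = NULL,
                             use_covariates = TRUE) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(genotypes, "GenotypeMatrix"))
  stopifnot(all(expr$sample_ids == covs$sample_id))
  codes <- genotypes$codes[, expr$sample_ids, drop = FALSE]
  maf <- apply(codes, 1L, function(v) {
    if (all(is.na(v))) NA_real_ else compute_maf(v)
  })
  pass <- !is.na(maf) & maf > maf_min
  if (!any(pass)) {
    warning("no SNPs pass MAF > ", maf_min)
    empty <- data.frame(unit_id = character(0), snp_id = character(0),
                        gene_id = character(0), estimate = numeric(0),
                        stderr = numeric(0), tstat = numeric(0),
                        pvalue = numeric(0), flag = character(0))
    attr(empty, "n_pairs_tested") <- 0L
    return(empty)
  }
  snp_ids <- genotypes$snp_ids[pass]
  n_genes <- min(n_genes, length(expr$gene_ids))
  genes_used <- with_seed(seed,
                          sort(sample(expr$gene_ids, n_genes)))
  if (is.null(pairs)) {
    if (is.null(gene_pos)) {
      stop("supply either an explicit pair list or gene_pos for cis pairing")
    }
    pairs <- cis_pairs(snp_ids, genotypes$snp_meta, genes_used, gene_pos,
                       cis_window)
  } else {
    pairs <- pairs[pairs$snp_id %in% snp_ids &
                     pairs$gene_id %in% genes_used, , drop = FALSE]
  }
  covmat <- if (use_covariates) {
    cbind(sex = sex_to_numeric(covs$sex), bmi = as.numeric(covs$bmi))
  } else NULL
  if (!is.null(factors) && ncol(factors) > 0L) {
    covmat <- cbind(covmat, factors)
  }
  rows <- vector("list", nrow(pairs))
  pvals <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    fit <- suppressMessages(fit_interaction_model(
      expr$values[pairs$gene_id[i], ],
      codes[pairs$snp_id[i], ],
      covs$age, covs = covmat))
    if (is.null(fit)) next
    pvals[i] <- fit$pvalue
    rows[[i]] <- cbind(data.frame(
      unit_id = paste0(pairs$snp_id[i], ":", pairs$gene_id[i]),
      snp_id = pairs$snp_id[i], gene_id = pairs$gene_id[i],
      stringsAsFactors = FALSE), fit)
  }
  tab <- do.call(rbind, Filter(Negate(is.null), rows))
  all_p <- if (is.null(tab)) numeric(0) else
    stats::setNames(tab$pvalue, tab$unit_id)
  if (is.null(tab)) {
    out <- data.frame(unit_id = character(0), snp_id = character(0),
                      gene_id = character(0), estimate = numeric(0),
                      stderr = numeric(0), tstat = numeric(0),
                      pvalue = numeric(0), flag = character(0))
  } else {
    out <- tab[tab$pvalue < p_report, , drop = FALSE]
    out <- out[order(out$pvalue),
               c("unit_id", "snp_id", "gene_id", "estimate", "stderr",
                 "tstat", "pvalue"), drop = FALSE]
    out$flag <- if (nrow(out)) "nominal" else character(0)
    rownames(out) <- NULL
  }
  attr(out, "n_pairs_tested") <- sum(!is.na(pvals))
  attr(out, "genes_used") <- genes_used
  attr(out, "all_pvalues") <- all_p
  out
}

cis_pairs <- function(snp_ids, snp_meta, gene_ids, gene_pos, window) {
  gp <- gene_pos[gene_pos$gene_id %in% gene_ids, , drop = FALSE]
  sm <- snp_meta[snp_meta$snp_id %in% snp_ids, , drop = FALSE]
  out <- lapply(seq_len(nrow(gp)), function(i) {
    hit <- sm$chrom == gp$chrom[i] & abs(sm$pos - gp$pos[i]) <= window
    if (!any(hit)) return(NULL)
    data.frame(snp_id = sm$snp_id[hit], gene_id = gp$gene_id[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out)) {
    data.frame(snp_id = character(0), gene_id = character(0))
  } else out
}
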