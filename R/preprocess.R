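#' Restrict an expression matrix and covariate table to one cohort
#'
#' Keeps samples matching an ancestry label and a region label; the study
#' design analyzes donors of European ancestry within each of 13 brain
#' regions separately. `"*"` acts as a wildcard for either filter.
#'
#' @param expr an [expression_matrix()].
#' @param covs covariate data frame ([read_covariates()]).
#' @param ancestry_keep ancestry label to retain, or `"*"` for all.
#' @param region region label to retain, or `"*"` for all.
#' @return A list with elements `expr` and `covs`, samples in covariate-table
#'   order.
#' @export
filter_samples <- function(expr, covs, ancestry_keep = "*", region = "*") {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!all(expr$sample_ids %in% covs$sample_id)) {
    missing <- setdiff(expr$sample_ids, covs$sample_id)
    stop("expression sample(s) absent from covariate table: ", missing[1L])
  }
  keep <- covs$sample_id %in% expr$sample_ids
  if (ancestry_keep != "*") keep <- keep & covs$ancestry == ancestry_keep
  if (region != "*") keep <- keep & covs$region == region
  covs2 <- covs[keep, , drop = FALSE]
  if (nrow(covs2) == 0L) {
    stop("no samples survive ancestry='", ancestry_keep,
         "', region='", region, "'")
  }
  values <- expr$values[, covs2$sample_id, drop = FALSE]
  list(expr = expression_matrix(values, state = expr$state), covs = covs2)
}

#' Drop the lowest-expressed fraction of genes
#'
#' Removes the `ceiling(fraction * G)` genes with the smallest mean
#' expression across samples (default 10%), as a pre-normalization filter on
#' the raw scale. Ties at the cutoff are broken by gene-id lexicographic
#' order so the result is deterministic.
#'
#' @param expr an [expression_matrix()] with `state = "rpkm"`.
#' @param fraction fraction of genes to drop, in `[0, 1)`.
#' @return The filtered [expression_matrix()], remaining gene order
#'   preserved.
#' @export
filter_low_expression <- function(expr, fraction = 0.10) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (fraction >= 1) stop("fraction must be < 1")
  if (fraction < 0) stop("fraction must be >= 0")
  g <- length(expr$gene_ids)
  n_drop <- ceiling(fraction * g)
  if (n_drop == 0L) return(expr)
  means <- rowMeans(expr$values)
  ord <- order(means, expr$gene_ids)       # ties: lexicographic gene id
  drop_ids <- expr$gene_ids[ord[seq_len(n_drop)]]
  keep <- !(expr$gene_ids %in% drop_ids)
  expression_matrix(expr$values[keep, , drop = FALSE], state = expr$state)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common reference distribution
#' formed by the row means of the column-sorted data. Ties within a column
#' receive the mean of the reference values their ranks span, so the map is
#' deterministic and rank-preserving within each column.
#'
#' @param expr an [expression_matrix()] with at least 2 samples.
#' @return An [expression_matrix()] in the same state with exchangeable
#'   column distributions.
#' @export
quantile_normalize <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  x <- expr$values
  if (ncol(x) < 2L) stop("quantile normalization needs >= 2 samples")
  sorted <- apply(x, 2L, sort)
  ref <- rowMeans(sorted)
  cs <- c(0, cumsum(ref))
  out <- apply(x, 2L, function(col) {
    # a tie group occupying sorted positions a..b gets mean(ref[a:b])
    lo <- rank(col, ties.method = "min")
    hi <- rank(col, ties.method = "max")
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  dimnames(out) <- dimnames(x)
  res <- expression_matrix(out, state = expr$state)
  attr(res, "quantile_normalized") <- TRUE
  res
}

#' Log2-transform expression values
#'
#' Applies `log2(value + pseudocount)` entrywise and advances the state tag
#' to `"lognorm"`. Calling this directly on raw (state `"rpkm"`) data
#' without quantile normalization is permitted but flagged with a message,
#' since the standard pipeline order is filter, quantile-normalize, then
#' log2.
#'
#' @param expr an [expression_matrix()] with non-negative values.
#' @param pseudocount positive offset added before the log (default 1).
#' @return An [expression_matrix()] with `state = "lognorm"`.
#' @export
log2_transform <- function(expr, pseudocount = 1) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (any(expr$values < 0)) stop("negative expression value; log2 undefined")
  if (expr$state == "rpkm" && !isTRUE(attr(expr, "quantile_normalized"))) {
    message("log2_transform applied to raw values without quantile ",
            "normalization (non-standard order)")
  }
  out <- log2(expr$values + pseudocount)
  expression_matrix(out, state = "lognorm")
}

#' Run the standard per-region normalization
#'
#' Convenience wrapper applying the canonical order: low-expression filter
#' on raw means, quantile normalization, log2 transform.
#'
#' @inheritParams filter_low_expression
#' @inheritParams log2_transform
#' @return An [expression_matrix()] with `state = "lognorm"`.
#' @export
preprocess_expression <- function(expr, fraction = 0.10, pseudocount = 1) {
  log2_transform(quantile_normalize(filter_low_expression(expr, fraction)),
                 pseudocount = pseudocount)
}
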