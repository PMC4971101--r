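#' Split donors into young and old age groups
#'
#' Young is age `<= boundary`, old is above. The default boundary of 60
#' gives the young 20-60 / old 61-70 split used for the main differential
#' variability scans; `boundary = 59` gives the alternative young 20-59 /
#' old 60-70 split (both appear in the study design; neither is privileged
#' beyond this documented default).
#'
#' @param ages ages in years.
#' @param boundary last age counted as young (default 60).
#' @param min_size smallest allowed group (default 2; a single observation
#'   has an identically zero absolute deviation, which is degenerate).
#' @return Factor with levels `young`, `old`.
#' @export
assign_age_groups <- function(ages, boundary = 60, min_size = 2L) {
  young <- ages <= boundary
  if (!any(young)) stop("empty young group at boundary ", boundary)
  if (all(young)) stop("empty old group at boundary ", boundary)
  g <- factor(ifelse(young, "young", "old"), levels = c("young", "old"))
  small <- names(which(table(g) < min_size))
  if (length(small)) {
    stop("age group '", small[1L], "' has fewer than ", min_size,
         " samples; absolute deviations would be degenerate")
  }
  g
}

#' Levene's test for equal dispersion between groups
#'
#' One-way ANOVA F-ratio on the absolute deviations
#' \eqn{z_{kj} = |x_{kj} - \bar{x}_{k\cdot}|} from the group means (the
#' classical mean-centered form; `center = "median"` gives the
#' Brown-Forsythe variant). When every within-group deviation is zero but
#' the groups differ, the F statistic is infinite; this is reported with a
#' `degenerate` flag and P = 0 rather than an error.
#'
#' @param x numeric vector of observations (for expression, one gene).
#' @param groups factor of group labels (ordered young, old for direction
#'   calls).
#' @param center `"mean"` (default) or `"median"`.
#' @param unit_id label carried into the result.
#' @return An object of class `levene_test`: `F`, `df` (g-1, n-g),
#'   `pvalue`, `direction` (`"increase"` when the last group's variance
#'   exceeds the first's), `degenerate`, group sizes and variances.
#' @export
levene_univariate <- function(x, groups, center = c("mean", "median"),
                              unit_id = NA_character_) {
  center <- match.arg(center)
  groups <- droplevels(as.factor(groups))
  g <- nlevels(groups)
  if (g < 2L) stop("need at least 2 groups")
  sizes <- table(groups)
  if (min(sizes) < 3L) stop("every group must have >= 3 observations")
  centre_fun <- if (center == "mean") mean else stats::median
  centers <- tapply(x, groups, centre_fun)
  z <- abs(x - centers[groups])
  res <- anova_f(z, groups)
  vars <- tapply(x, groups, stats::var)
  direction <- if (vars[g] > vars[1L]) "increase" else "decrease"
  structure(list(unit_id = unit_id, F = res$F, df = res$df,
                 pvalue = res$pvalue, direction = direction,
                 degenerate = res$degenerate,
                 group_sizes = as.integer(sizes),
                 group_variances = as.numeric(vars),
                 center = center),
            class = "levene_test")
}

#' @export
print.levene_test <- function(x, ...) {
  cat(sprintf("Levene test%s: F(%d, %d) = %.4g, P = %.4g, dispersion %s\n",
              if (is.na(x$unit_id)) "" else paste0(" [", x$unit_id, "]"),
              x$df[1L], x$df[2L], x$F, x$pvalue, x$direction))
  if (x$degenerate) cat("  (degenerate: zero within-group deviation)\n")
  invisible(x)
}

## one-way ANOVA F on a response, with the degenerate zero-SSW case handled
anova_f <- function(z, groups) {
  n <- length(z)
  g <- nlevels(groups)
  grand <- mean(z)
  means <- tapply(z, groups, mean)
  sizes <- tabulate(groups)
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum((z - means[groups])^2)
  df <- c(g - 1L, n - g)
  if (ssw <= .Machine$double.eps * sum(z^2) || ssw == 0) {
    if (ssb > 0) {
      return(list(F = Inf, df = df, pvalue = 0, degenerate = TRUE))
    }
    return(list(F = 0, df = df, pvalue = 1, degenerate = TRUE))
  }
  Fstat <- (ssb / df[1L]) / (ssw / df[2L])
  list(F = Fstat, df = df,
       pvalue = stats::pf(Fstat, df[1L], df[2L], lower.tail = FALSE),
       degenerate = FALSE)
}

#' Per-gene differential-variability scan
#'
#' Runs the univariate Levene test on every gene between the age groups and
#' adjusts P-values by Benjamini-Hochberg. Degenerate (infinite-F) genes
#' are reported but excluded from the BH pool, since their P of exactly 0
#' is an artifact of zero within-group deviation.
#'
#' @param expr an [expression_matrix()] (default input state: residual).
#' @param groups factor from [assign_age_groups()].
#' @param fdr FDR level for the significance calls (default 0.05).
#' @param center deviation center, `"mean"` or `"median"`.
#' @return Data frame per gene: `unit_id`, `F`, `pvalue`, `adjusted`,
#'   `direction`, `significant`, `degenerate`; attribute
#'   `direction_counts` tallies significant increases/decreases.
#' @export
dv_scan <- function(expr, groups, fdr = 0.05, center = "mean") {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  res <- lapply(seq_along(expr$gene_ids), function(i) {
    lt <- levene_univariate(expr$values[i, ], groups, center = center,
                            unit_id = expr$gene_ids[i])
    data.frame(unit_id = lt$unit_id, F = lt$F, pvalue = lt$pvalue,
               direction = lt$direction, degenerate = lt$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted <- NA_real_
  pool <- !out$degenerate
  out$adjusted[pool] <- stats::p.adjust(out$pvalue[pool], method = "BH")
  out$significant <- !is.na(out$adjusted) & out$adjusted <= fdr
  attr(out, "direction_counts") <- c(
    increase = sum(out$significant & out$direction == "increase"),
    decrease = sum(out$significant & out$direction == "decrease")
  )
  out
}

#' Minimum covariance determinant location and scatter
#'
#' FAST-MCD: seeded random elemental starts (p + 1 points each), two
#' concentration steps per start (re-estimate mean and covariance from the
#' h observations with smallest current Mahalanobis distances -- a step
#' that provably never increases the covariance determinant), full
#' refinement of the best candidates, smallest determinant wins. With
#' `h = n` the estimate is exactly the classical mean and covariance. For
#' `h < n` the scatter is rescaled by the chi-square consistency factor so
#' robust distances are comparable to classical ones under normality.
#'
#' @param X samples x p numeric matrix, `n > p`.
#' @param h subset size in `[floor((n+p+1)/2), n]`; default
#'   `floor(0.75 n)`.
#' @param seed integer seed for the elemental starts.
#' @param n_starts number of elemental starts (default 500).
#' @param n_keep candidates refined to convergence (default 10).
#' @return An object of class `mcd_fit`: `center`, `scatter`, `h`,
#'   `distances` (robust Mahalanobis distance per sample), `best_subset`,
#'   and `det_history` (log-determinant sequence of the winning
#'   refinement, non-increasing by construction).
#' @export
mcd_estimate <- function(X, h = NULL, seed = 1L, n_starts = 500L,
                         n_keep = 10L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more samples than variables (n = ", n,
                   ", p = ", p, ")")
  if (is.null(h)) h <- floor(0.75 * n)
  h_min <- floor((n + p + 1) / 2)
  if (h < h_min || h > n) {
    stop("h must lie in [", h_min, ", ", n, "]")
  }
  if (h == n) {
    center <- colMeans(X)
    scatter <- stats::cov(X)
    d <- sqrt(stats::mahalanobis(X, center, scatter))
    return(structure(list(center = center, scatter = scatter, h = h,
                          distances = d, best_subset = seq_len(n),
                          det_history = numeric(0), consistency = 1),
                     class = "mcd_fit"))
  }
  subset_fit <- function(idx) {
    m <- colMeans(X[idx, , drop = FALSE])
    S <- stats::cov(X[idx, , drop = FALSE])
    ld <- determinant(S, logarithm = TRUE)
    if (ld$sign <= 0 || !is.finite(ld$modulus)) return(NULL)
    list(center = m, scatter = S, logdet = as.numeric(ld$modulus))
  }
  c_step <- function(fit) {
    d2 <- tryCatch(stats::mahalanobis(X, fit$center, fit$scatter),
                   error = function(e) NULL)   # ill-conditioned subset
    if (is.null(d2)) return(list(fit = NULL, idx = NULL))
    idx <- order(d2)[seq_len(h)]
    list(fit = subset_fit(idx), idx = idx)
  }
  candidates <- with_seed(seed, {
    out <- vector("list", n_starts)
    for (s in seq_len(n_starts)) {
      fit <- NULL
      for (try in 1:25) {   # singular elemental subsets: retry
        idx0 <- sample.int(n, p + 1L)
        fit <- subset_fit(idx0)
        if (!is.null(fit)) break
      }
      if (is.null(fit)) next
      ok <- TRUE
      for (cs in 1:2) {
        stp <- c_step(fit)
        if (is.null(stp$fit)) { ok <- FALSE; break }
        fit <- stp$fit
        fit$idx <- stp$idx
      }
      if (ok) out[[s]] <- fit
    }
    Filter(Negate(is.null), out)
  })
  if (!length(candidates)) {
    stop("all candidate subsets gave singular covariance; try a larger h")
  }
  ld <- vapply(candidates, `[[`, 0, "logdet")
  best <- candidates[order(ld)[seq_len(min(n_keep, length(candidates)))]]
  refine <- function(fit) {
    history <- fit$logdet
    repeat {
      stp <- c_step(fit)
      if (is.null(stp$fit)) break
      new_fit <- stp$fit
      new_fit$idx <- stp$idx
      history <- c(history, new_fit$logdet)
      if (new_fit$logdet >= fit$logdet - 1e-12) { fit <- new_fit; break }
      fit <- new_fit
    }
    fit$history <- history
    fit
  }
  refined <- lapply(best, refine)
  winner <- refined[[which.min(vapply(refined, `[[`, 0, "logdet"))]]
  # consistency rescaling: median robust distance^2 matches chisq(p) median
  d2_raw <- stats::mahalanobis(X, winner$center, winner$scatter)
  cf <- stats::median(d2_raw) / stats::qchisq(0.5, df = p)
  scatter <- winner$scatter * cf
  d <- sqrt(d2_raw / cf)
  structure(list(center = winner$center, scatter = scatter, h = h,
                 distances = d, best_subset = sort(winner$idx),
                 det_history = winner$history, consistency = cf),
            class = "mcd_fit")
}

#' @export
print.mcd_fit <- function(x, ...) {
  cat("MCD fit: p =", length(x$center), ", h =", x$h,
      if (length(x$det_history)) sprintf(", log|S| = %.4g",
                                         x$det_history[length(x$det_history)])
      else " (classical)", "\n")
  invisible(x)
}

#' Robust Mahalanobis distances to a fitted centroid
#'
#' \eqn{MD_i = \sqrt{(x_i - c)^T \Psi^{-1} (x_i - c)}} with the location
#' `c` and scatter \eqn{\Psi} from an [mcd_estimate()] fit, quantifying
#' each sample's distance to the multivariate centroid.
#'
#' @param X samples x p matrix in the model's column space.
#' @param model an `mcd_fit`.
#' @return Non-negative distance vector.
#' @export
robust_md <- function(X, model) {
  stopifnot(inherits(model, "mcd_fit"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$center)) {
    stop("X has ", ncol(X), " columns; model was fitted on ",
         length(model$center))
  }
  ev <- eigen(model$scatter, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("scatter matrix is not positive definite")
  sqrt(stats::mahalanobis(X, model$center, model$scatter))
}

#' Multivariate Levene test on a gene set
#'
#' The multivariate generalization of Levene's test: each sample's robust
#' Mahalanobis distance to the pooled centroid is computed (MCD location
#' and scatter by default; `estimator = "classical"` uses the sample mean
#' and covariance), and the ANOVA F-ratio compares those distances between
#' groups. The distances play the role of the univariate test's absolute
#' deviations \eqn{z_{kj} = |x_{kj} - \bar x_k|} -- both measure how far
#' each sample sits from a center, so a group with larger dispersion has
#' systematically larger values. Direction follows the group mean
#' distances: a larger mean MD in the old group is an `"increase"` in
#' dispersion.
#'
#' @param X samples x p matrix (p >= 2 genes of one set).
#' @param groups factor from [assign_age_groups()].
#' @param seed seed passed to [mcd_estimate()].
#' @param estimator `"mcd"` (default) or `"classical"`.
#' @param h_fraction MCD subset fraction (default 0.75).
#' @param unit_id label carried into the result.
#' @return A `levene_test` object with an `md_group_means` element.
#' @export
levene_multivariate <- function(X, groups, seed = 1L,
                                estimator = c("mcd", "classical"),
                                h_fraction = 0.75, unit_id = NA_character_) {
  estimator <- match.arg(estimator)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p >= n) stop("more genes than samples (p = ", p, ", n = ", n,
                   "); reduce the set")
  groups <- droplevels(as.factor(groups))
  if (any(table(groups) <= p + 2L)) {
    stop("each group needs more than p + 2 samples")
  }
  h <- if (estimator == "classical") n else floor(h_fraction * n)
  model <- mcd_estimate(X, h = h, seed = seed)
  md <- model$distances
  md_means <- tapply(md, groups, mean)
  res <- anova_f(md, groups)
  direction <- if (md_means[nlevels(groups)] > md_means[1L])
    "increase" else "decrease"
  structure(list(unit_id = unit_id, F = res$F, df = res$df,
                 pvalue = res$pvalue, direction = direction,
                 degenerate = res$degenerate,
                 group_sizes = as.integer(table(groups)),
                 md_group_means = as.numeric(md_means),
                 estimator = estimator, model = model),
            class = "levene_test")
}

#' Gene-set differential-variability scan
#'
#' Applies the multivariate Levene test to every gene set with at least 2
#' genes present in the matrix (and few enough genes for the sample size),
#' then adjusts across tested sets by Benjamini-Hochberg. Output columns
#' mirror a per-set report: term, genes, dispersion direction, P, FDR.
#'
#' @param expr an [expression_matrix()] (default input state: residual).
#' @param sets a [gene_set_collection()].
#' @param groups factor from [assign_age_groups()].
#' @param fdr FDR level for the significance calls (default 0.05).
#' @param seed seed for the MCD starts.
#' @param estimator `"mcd"` or `"classical"`.
#' @return Data frame per tested set (`unit_id`, `genes`, `n_genes`, `F`,
#'   `pvalue`, `adjusted`, `direction`, `significant`) sorted by P;
#'   attribute `skipped` lists untestable sets with reasons.
#' @export
dv_geneset_scan <- function(expr, sets, groups, fdr = 0.05, seed = 1L,
                            estimator = "mcd") {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  groups <- droplevels(as.factor(groups))
  rows <- list()
  skipped <- character(0)
  n <- length(expr$sample_ids)
  for (id in names(sets)) {
    present <- intersect(sets[[id]], expr$gene_ids)
    if (length(present) < 2L) {
      skipped <- c(skipped, stats::setNames("fewer than 2 genes present", id))
      next
    }
    if (length(present) >= n ||
        any(table(groups) <= length(present) + 2L)) {
      skipped <- c(skipped, stats::setNames("set too large for sample size", id))
      next
    }
    lt <- levene_multivariate(t(expr$values[present, , drop = FALSE]),
                              groups, seed = seed, estimator = estimator,
                              unit_id = id)
    rows[[id]] <- data.frame(
      unit_id = id, genes = paste(present, collapse = ","),
      n_genes = length(present), F = lt$F, pvalue = lt$pvalue,
      direction = lt$direction, degenerate = lt$degenerate,
      stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    message(length(skipped), " set(s) skipped")
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit_id = character(0), genes = character(0),
               n_genes = integer(0), F = numeric(0), pvalue = numeric(0),
               direction = character(0), degenerate = logical(0))
  out$adjusted <- NA_real_
  pool <- !out$degenerate
  out$adjusted[pool] <- stats::p.adjust(out$pvalue[pool], method = "BH")
  out$significant <- !is.na(out$adjusted) & out$adjusted <= fdr
  out <- out[order(out$pvalue), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
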