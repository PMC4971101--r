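#' Estimate global hidden expression factors jointly with known covariates
#'
#' First step of the two-step confounder correction. Each gene is regressed
#' on the known donor covariates (sex, BMI, ischemic time when available,
#' and age when `include_age = TRUE`); the fitted coefficients are reported
#' as the model's covariate effects. Latent factors are then estimated by
#' alternating least squares, initialized from the singular value
#' decomposition of the matrix with only the *non-age* covariates removed:
#' age-related structure (true age responses and age-correlated technical
#' confounders alike) must remain visible to the factor search so it can
#' surface as factors and be flagged by the downstream age-correlation
#' filter, rather than being silently absorbed into per-gene age
#' coefficients where the filter cannot see it. With the SVD
#' initialization the alternation starts at the best rank-K approximation
#' and the procedure is fully deterministic.
#'
#' Factor scores are standardized to unit sample variance and each factor's
#' sign is fixed by forcing its largest-magnitude loading positive.
#'
#' @param expr an [expression_matrix()] with `state = "lognorm"` (or
#'   `"residual"` for pathway-level use).
#' @param covs covariate data frame, or `NULL` for an intercept-only design.
#' @param K number of factors, at most 15 by convention; `K = 0` returns
#'   only the covariate fits.
#' @param include_age include age among the known covariates (default TRUE).
#' @param tol relative convergence tolerance on the Frobenius reconstruction
#'   error (default 1e-8).
#' @param max_iter maximum alternation sweeps (default 500).
#' @return An object of class `FactorModel`: factor `scores` (samples x K,
#'   unit variance), `loadings` (genes x K), `covariate_effects` (genes x C),
#'   the covariate design used, and placeholders for the age-correlation
#'   verdicts filled by [filter_age_correlated_factors()].
#' @export
fit_hidden_factors <- function(expr, covs, K = 15, include_age = TRUE,
                               tol = 1e-8, max_iter = 500L) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  Y <- expr$values
  n <- ncol(Y)
  if (is.null(covs)) {
    X <- matrix(1, n, 1L, dimnames = list(NULL, "intercept"))
  } else {
    stopifnot(all(colnames(Y) == covs$sample_id))
    X <- covariate_design(covs, include_age = include_age)
  }
  C <- ncol(X)
  # the residual matrix has rank at most min(G, n - C); one factor fewer
  # keeps the alternation well posed
  max_K <- min(nrow(Y), n - C) - 1L
  if (K > max_K) {
    stop("K = ", K, " exceeds the rank bound; use K <= ", max_K)
  }
  fit <- ols_multi(Y, X)
  if (include_age && "age" %in% colnames(X)) {
    X_disc <- X[, colnames(X) != "age", drop = FALSE]
    R <- ols_multi(Y, X_disc)$residuals    # age structure kept discoverable
  } else {
    R <- fit$residuals
  }
  scores <- matrix(0, n, 0L)
  loadings <- matrix(0, nrow(Y), 0L)
  iterations <- 0L
  if (K > 0L) {
    sv <- svd(R)
    # exactly low-rank residuals support fewer factors than requested
    num_rank <- sum(sv$d > sv$d[1L] * 1e-10)
    if (K > num_rank) {
      message("residual matrix has rank ", num_rank,
              "; K reduced from ", K)
      K <- num_rank
    }
    L <- sv$u[, seq_len(K), drop = FALSE] %*%
      diag(sv$d[seq_len(K)], K, K)               # genes x K
    Fm <- sv$v[, seq_len(K), drop = FALSE]       # samples x K
    err_prev <- Inf
    for (it in seq_len(max_iter)) {
      # loadings given scores, then scores given loadings (both OLS)
      L <- R %*% Fm %*% solve(crossprod(Fm))
      Fm <- t(R) %*% L %*% solve(crossprod(L))
      err <- norm(R - L %*% t(Fm), "F")
      iterations <- it
      if (is.finite(err_prev) &&
          abs(err_prev - err) <= tol * max(err_prev, .Machine$double.eps)) {
        break
      }
      err_prev <- err
    }
    # standardize scores to unit variance, move scale into loadings
    sds <- apply(Fm, 2L, stats::sd)
    sds[sds == 0] <- 1
    Fm <- sweep(Fm, 2L, sds, "/")
    L <- sweep(L, 2L, sds, "*")
    # sign convention: largest-|loading| entry positive
    signs <- vapply(seq_len(K), function(k) {
      sign(L[which.max(abs(L[, k])), k])
    }, 0)
    signs[signs == 0] <- 1
    Fm <- sweep(Fm, 2L, signs, "*")
    L <- sweep(L, 2L, signs, "*")
    colnames(Fm) <- colnames(L) <- paste0("factor", seq_len(K))
    rownames(Fm) <- colnames(Y)
    rownames(L) <- rownames(Y)
    scores <- Fm
    loadings <- L
  }
  structure(list(
    scores = scores,
    loadings = loadings,
    covariate_effects = fit$coef,
    covariate_names = colnames(X),
    design = X,
    K = K,
    iterations = iterations,
    age_corr = rep(NA_real_, K),
    age_corr_p = rep(NA_real_, K),
    kept = rep(NA, K),
    sample_ids = colnames(Y)
  ), class = "FactorModel")
}

#' @export
print.FactorModel <- function(x, ...) {
  cat("FactorModel:", x$K, "hidden factor(s),",
      length(x$covariate_names), "known covariate(s)\n")
  if (x$K > 0L && !anyNA(x$kept)) {
    cat("  kept (age-uncorrelated):", sum(x$kept), "of", x$K, "\n")
  }
  invisible(x)
}

#' Flag and drop hidden factors correlated with age
#'
#' Second step of the correction: each factor's Pearson correlation with
#' donor age is tested (t-transform with n - 2 degrees of freedom,
#' two-sided) and factors with P below the threshold are excluded, so that
#' residualization cannot remove genuine age signal along with technical
#' structure.
#'
#' @param model a `FactorModel` from [fit_hidden_factors()].
#' @param age numeric vector of ages, one per sample.
#' @param p_threshold exclusion threshold on the correlation-test P-value
#'   (default 0.05).
#' @return The model with `age_corr`, `age_corr_p` and `kept` filled in.
#' @export
filter_age_correlated_factors <- function(model, age, p_threshold = 0.05) {
  stopifnot(inherits(model, "FactorModel"))
  if (length(age) != nrow(model$scores) && model$K > 0L) {
    stop("age length must equal the sample count")
  }
  if (stats::sd(age) == 0) {
    stop("age vector is constant; correlation with factors is undefined")
  }
  if (model$K == 0L) return(model)
  tests <- lapply(seq_len(model$K), function(k) {
    stats::cor.test(model$scores[, k], age, method = "pearson")
  })
  model$age_corr <- vapply(tests, function(t) unname(t$estimate), 0)
  model$age_corr_p <- vapply(tests, function(t) t$p.value, 0)
  model$kept <- model$age_corr_p >= p_threshold
  model$p_threshold <- p_threshold
  model
}

#' Kept-factor score matrix
#'
#' @param model a filtered `FactorModel`.
#' @return samples x N matrix of the scores of age-uncorrelated factors
#'   (possibly zero columns).
#' @export
kept_factor_scores <- function(model) {
  stopifnot(inherits(model, "FactorModel"))
  if (model$K == 0L) return(model$scores)
  if (anyNA(model$kept)) {
    stop("run filter_age_correlated_factors() before extracting kept factors")
  }
  model$scores[, model$kept, drop = FALSE]
}

#' Regress out kept factors and non-age covariates
#'
#' Final step: each gene is regressed by ordinary least squares on an
#' intercept, the kept (age-uncorrelated) factor scores, and the non-age
#' known covariates; the residuals become the corrected expression matrix.
#' Age is never among the regressors here, by construction.
#'
#' @param expr the [expression_matrix()] the model was fitted on.
#' @param model a filtered `FactorModel`.
#' @param covs covariate data frame (same samples), or `NULL` to regress on
#'   the kept factors only.
#' @return An [expression_matrix()] with `state = "residual"`.
#' @export
residualize <- function(expr, model, covs = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(model, "FactorModel"))
  if (!identical(expr$sample_ids, model$sample_ids)) {
    stop("model was fitted on different samples")
  }
  Fk <- kept_factor_scores(model)
  parts <- list(intercept = rep(1, ncol(expr$values)))
  if (ncol(Fk) > 0L) parts$factors <- Fk
  if (!is.null(covs)) {
    Xc <- covariate_design(covs, include_age = FALSE, intercept = FALSE)
    parts$covs <- Xc
  }
  X <- do.call(cbind, parts)
  colnames(X) <- c("intercept",
                   if (ncol(Fk) > 0L) colnames(Fk),
                   if (!is.null(covs)) colnames(parts$covs))
  fit <- ols_multi(expr$values, X)
  out <- fit$residuals
  dimnames(out) <- dimnames(expr$values)
  expression_matrix(out, state = "residual")
}

#' Full two-step confounder correction
#'
#' Convenience wrapper: fit up to `K` hidden factors with age included as a
#' known covariate, drop the factors whose Pearson correlation with age has
#' P below `p_threshold`, and residualize on the survivors plus non-age
#' covariates.
#'
#' @inheritParams fit_hidden_factors
#' @inheritParams filter_age_correlated_factors
#' @return A list with `expr` (state `"residual"`) and `model` (the filtered
#'   `FactorModel`).
#' @export
correct_confounders <- function(expr, covs, K = 15, p_threshold = 0.05,
                                tol = 1e-8, max_iter = 500L) {
  model <- fit_hidden_factors(expr, covs, K = K, include_age = TRUE,
                              tol = tol, max_iter = max_iter)
  model <- filter_age_correlated_factors(model, covs$age, p_threshold)
  list(expr = residualize(expr, model, covs), model = model)
}
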