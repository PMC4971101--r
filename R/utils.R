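#' @keywords internal
"_PACKAGE"

## Multi-response ordinary least squares on a shared design.
##
## Y is units x samples (each row one response), X is samples x p.
## One QR factorization serves every row; this is what makes the per-gene
## scans tractable at transcriptome scale.
ols_multi <- function(Y, X, check_rank = TRUE) {
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1L)
  n <- ncol(Y)
  stopifnot(nrow(X) == n)
  p <- ncol(X)
  df <- n - p
  if (df <= 0L) {
    stop("degrees of freedom would be ", df,
         ": need more samples than regressors (n = ", n, ", p = ", p, ")")
  }
  qx <- qr(X)
  if (check_rank && qx$rank < p) {
    bad <- colnames(X)[setdiff(seq_len(p), qx$pivot[seq_len(qx$rank)])]
    stop("design matrix is rank-deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  coef <- t(qr.coef(qx, t(Y)))            # units x p
  fitted <- coef %*% t(X)
  resid <- Y - fitted
  sigma2 <- rowSums(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qx)[seq_len(p), seq_len(p), drop = FALSE])
  # undo any pivoting
  piv <- qx$pivot
  xtx_inv <- xtx_inv[order(piv), order(piv), drop = FALSE]
  se <- sqrt(outer(sigma2, diag(xtx_inv)))
  tstat <- coef / se
  pval <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  colnames(coef) <- colnames(se) <- colnames(tstat) <- colnames(pval) <- colnames(X)
  list(coef = coef, se = se, tstat = tstat, pvalue = pval,
       residuals = resid, fitted = fitted, df = df, sigma2 = sigma2)
}

## Sex is coded female = 0, male = 1 for regression; any consistent binary
## coding gives identical t and P for every coefficient.
sex_to_numeric <- function(sex) {
  as.numeric(sex == "male")
}

## Known-covariate design (samples x C) from a SampleTable, optionally with
## age; ischemic time enters only when the column is present and non-missing.
covariate_design <- function(covs, include_age = TRUE, intercept = TRUE) {
  cols <- list()
  if (intercept) cols$intercept <- rep(1, nrow(covs))
  if (include_age) cols$age <- as.numeric(covs$age)
  cols$sex <- sex_to_numeric(covs$sex)
  cols$bmi <- as.numeric(covs$bmi)
  if (!is.null(covs$ischemic_time) && !anyNA(covs$ischemic_time)) {
    cols$ischemic_time <- as.numeric(covs$ischemic_time)
  }
  do.call(cbind, cols)
}

## seeded RNG scope: evaluate expr under a local seed without disturbing the
## caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
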