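make_structured_data <- function(n = 40, genes = 60, seed = 1,
                                 factor_age_r = 0, loading_sd = 0.5,
                                 noise_sd = 0) {
  set.seed(seed)
  covs <- toy_covs(n, seed = seed)
  u <- factor_age_r * scale(covs$age)[, 1] +
    sqrt(1 - factor_age_r^2) * rnorm(n)
  u <- as.numeric(scale(u))
  lam <- rnorm(genes, 0, loading_sd)
  beta_sex <- rnorm(genes, 0, 0.2)
  vals <- outer(beta_sex, as.numeric(covs$sex == "male")) +
    lam %*% t(u) +
    matrix(rnorm(genes * n, 0, noise_sd), genes, n)
  dimnames(vals) <- list(sprintf("G%03d", seq_len(genes)), covs$sample_id)
  list(expr = expression_matrix(vals, state = "lognorm"), covs = covs, u = u)
}

test_that("an exact rank-1 structure is recovered perfectly", {
  set.seed(1)
  covs <- toy_covs(40, seed = 1)
  # hidden structure orthogonal to the known covariates (pure latent signal)
  u <- as.numeric(scale(residuals(
    lm(rnorm(40) ~ I(covs$sex == "male") + covs$bmi))))
  lam <- rnorm(60, 0, 0.5)
  vals <- outer(rnorm(60, 0, 0.2), as.numeric(covs$sex == "male")) +
    lam %*% t(u)
  dimnames(vals) <- list(sprintf("G%03d", 1:60), covs$sample_id)
  em <- expression_matrix(vals, state = "lognorm")
  m <- fit_hidden_factors(em, covs, K = 1)
  expect_gt(abs(cor(m$scores[, 1], u)), 1 - 1e-8)
  expect_equal(apply(m$scores, 2, var), c(factor1 = 1), tolerance = 1e-8)
})

test_that("on pure noise the factor matches the top singular vector of the residual", {
  set.seed(3)
  covs <- toy_covs(30, seed = 3)
  vals <- matrix(rnorm(50 * 30), 50, 30,
                 dimnames = list(sprintf("G%02d", 1:50), covs$sample_id))
  em <- expression_matrix(vals, state = "lognorm")
  m <- fit_hidden_factors(em, covs, K = 1)
  # independent oracle: direct SVD of the residual from the same regression
  X <- cbind(1, covs$sex == "male", covs$bmi)  # non-age covariates
  R <- vals - vals %*% X %*% solve(crossprod(X)) %*% t(X)
  sv <- svd(R)
  expect_gt(abs(cor(m$scores[, 1], sv$v[, 1])), 1 - 1e-6)
  # and it cannot explain more variance than that singular value allows
  recon <- m$loadings %*% t(m$scores)
  expect_lte(norm(recon, "F"), sv$d[1] * 1.0000001)
})

test_that("K = 0 reduces to per-gene ordinary least squares", {
  d <- make_structured_data(noise_sd = 0.5)
  m <- fit_hidden_factors(d$expr, d$covs, K = 0)
  expect_identical(ncol(m$scores), 0L)
  X <- m$design
  # normal-equations oracle for a few genes
  for (i in c(1L, 7L, 33L)) {
    beta <- solve(crossprod(X), crossprod(X, d$expr$values[i, ]))
    expect_equal(unname(m$covariate_effects[i, ]), unname(drop(beta)),
                 tolerance = 1e-10)
  }
  expect_error(fit_hidden_factors(d$expr, d$covs, K = 50), "K <=")
})

test_that("age-correlated factors are excluded by the Pearson filter", {
  n <- 30
  covs <- toy_covs(n, seed = 11)
  m <- fit_hidden_factors(rand_expression(40, n, seed = 11), covs, K = 2)
  # overwrite scores with controlled vectors: age itself, and an orthogonal one
  age_c <- covs$age - mean(covs$age)
  orth <- residuals(lm(rnorm(n) ~ age_c))
  m$scores[, 1] <- scale(age_c)[, 1]
  m$scores[, 2] <- scale(orth)[, 1]
  m <- filter_age_correlated_factors(m, covs$age)
  expect_false(m$kept[1])                     # r = 1, P ~ 0
  expect_true(m$kept[2])                      # r = 0 -> P = 1
  expect_equal(m$age_corr_p[2], 1, tolerance = 1e-12)

  expect_error(filter_age_correlated_factors(m, rep(50, n)), "constant")
})

test_that("the correlation P matches the t-transform oracle (r=0.9, n=20)", {
  # construct two vectors with sample correlation exactly 0.9
  set.seed(5)
  a <- scale(rnorm(20))[, 1]
  b0 <- scale(residuals(lm(rnorm(20) ~ a)))[, 1]
  r <- 0.9
  f <- scale(r * a / sd(a) + sqrt(1 - r^2) * b0 / sd(b0))[, 1]
  expect_equal(cor(f, a), 0.9, tolerance = 1e-12)
  t_oracle <- 0.9 * sqrt(18) / sqrt(1 - 0.81)
  expect_equal(t_oracle, 8.76, tolerance = 1e-3)
  p_oracle <- 2 * pt(t_oracle, df = 18, lower.tail = FALSE)
  ct <- cor.test(f, a)
  expect_equal(ct$p.value, p_oracle, tolerance = 1e-12)
  expect_lt(p_oracle, 0.05)
})

test_that("residualization is an exact projection with age protection", {
  d <- make_structured_data(n = 50, genes = 40, seed = 21, noise_sd = 0.3)
  m <- fit_hidden_factors(d$expr, d$covs, K = 2)
  m <- filter_age_correlated_factors(m, d$covs$age)
  resid <- residualize(d$expr, m, d$covs)
  expect_identical(resid$state, "residual")

  kept <- kept_factor_scores(m)
  regs <- cbind(kept, sex = as.numeric(d$covs$sex == "male"),
                bmi = d$covs$bmi)
  max_cor <- max(abs(cor(t(resid$values), regs)))
  expect_lt(max_cor, 1e-10)

  # a gene that is exactly twice a kept factor residualizes to zero
  if (ncol(kept) > 0) {
    v <- d$expr$values
    v[1, ] <- 2 * kept[, 1]
    em2 <- expression_matrix(v, state = "lognorm")
    r2 <- residualize(em2, m, d$covs)
    expect_lt(max(abs(r2$values[1, ])), 1e-10)
  }

  # total variance never increases
  expect_lte(sum(apply(resid$values, 1, var)),
             sum(apply(d$expr$values, 1, var)))
})

test_that("age signal survives correction when factors are age-uncorrelated", {
  set.seed(31)
  n <- 80
  covs <- toy_covs(n, seed = 31)
  alpha <- 0.5
  vals <- t(replicate(200, alpha * covs$age + rnorm(n, 0, 5)))
  dimnames(vals) <- list(sprintf("G%03d", 1:200), covs$sample_id)
  em <- expression_matrix(vals, state = "lognorm")
  cc <- correct_confounders(em, covs, K = 3)
  raw_r <- apply(vals, 1, function(y) cor(y, covs$age))
  res_r <- apply(cc$expr$values, 1, function(y) cor(y, covs$age))
  # mean correlation with age is retained within 10%
  expect_gt(mean(abs(res_r)) / mean(abs(raw_r)), 0.9)
})

test_that("factor fitting is deterministic", {
  d <- make_structured_data(n = 30, genes = 30, seed = 9, noise_sd = 0.4)
  m1 <- fit_hidden_factors(d$expr, d$covs, K = 3)
  m2 <- fit_hidden_factors(d$expr, d$covs, K = 3)
  expect_identical(m1$scores, m2$scores)
  expect_identical(m1$loadings, m2$loadings)
})
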