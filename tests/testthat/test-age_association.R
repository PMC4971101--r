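test_that("a noiseless age slope is recovered exactly", {
  age <- seq(21, 66, length.out = 10)
  y <- 0.5 * age
  fit <- fit_age_model(y, age)
  expect_equal(fit$alpha, 0.5, tolerance = 1e-12)
  expect_lt(fit$alpha_p, 1e-12)
})

test_that("coefficients match the normal-equations oracle on a full design", {
  set.seed(2)
  n <- 35
  covs <- toy_covs(n, seed = 2)
  fac <- matrix(rnorm(n * 2), n, 2,
                dimnames = list(NULL, c("factor1", "factor2")))
  y <- rnorm(n)
  fit <- fit_age_model(y, covs$age, covs$sex, covs$bmi, fac)
  X <- cbind(1, covs$age, as.numeric(covs$sex == "male"), covs$bmi, fac)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(fit$alpha, beta[2], tolerance = 1e-10)
  expect_equal(fit$mu, beta[1], tolerance = 1e-10)
  expect_equal(unname(fit$delta), unname(beta[5:6]), tolerance = 1e-10)

  # and the standard machinery agrees (independent cross-check)
  lmfit <- lm(y ~ covs$age + I(covs$sex == "male") + covs$bmi + fac)
  sm <- summary(lmfit)$coefficients
  expect_equal(fit$alpha_se, sm[2, 2], tolerance = 1e-10)
  expect_equal(fit$alpha_p, sm[2, 4], tolerance = 1e-10)

  # t-test P equals the 1-df partial F-test P
  f_drop <- anova(lm(y ~ I(covs$sex == "male") + covs$bmi + fac), lmfit)
  expect_equal(fit$alpha_p, f_drop$`Pr(>F)`[2], tolerance = 1e-10)
})

test_that("age_scan equals per-gene fits and guards rank deficiency", {
  em <- rand_expression(genes = 12, samples = 25, seed = 4)
  covs <- toy_covs(25, seed = 4)
  tab <- age_scan(em, covs)
  for (i in c(1L, 12L)) {
    f <- fit_age_model(em$values[i, ], covs$age, covs$sex, covs$bmi)
    expect_equal(tab$estimate[i], f$alpha, tolerance = 1e-12)
    expect_equal(tab$pvalue[i], f$alpha_p, tolerance = 1e-12)
  }
  covs2 <- covs
  covs2$bmi <- covs2$age   # collinear with age
  expect_error(age_scan(em, covs2), "rank-deficient")
})

test_that("BH tiers, directions and counts follow the step-up recursion", {
  fits <- data.frame(gene_id = paste0("g", 1:4),
                     estimate = c(2, -2, 1, -1),
                     stderr = 1, tstat = 1,
                     pvalue = c(0.005, 0.011, 0.02, 0.04))
  out <- call_age_genes(fits)
  expect_equal(out$adjusted, c(0.02, 0.022, 0.08 / 3, 0.04),
               tolerance = 1e-12)
  expect_identical(out$direction, c("up", "down", "up", "down"))
  counts <- attr(out, "counts")
  expect_identical(counts$total[counts$fdr == 0.05], 4L)

  flat <- data.frame(gene_id = paste0("g", 1:6), estimate = 1, stderr = 1,
                     tstat = 1, pvalue = rep(0.05, 6))
  expect_true(all(call_age_genes(flat)$adjusted == 0.05))

  expect_error(call_age_genes(fits[0, ]), "empty")
})

test_that("subsampling at full size reproduces the full analysis and is seeded", {
  sim <- simulate_dataset(40, 80, 5, seed = 6,
                          config = sim_config(n_confounders = 1))
  pre <- preprocess_expression(sim$expr)
  full_model <- fit_hidden_factors(pre, sim$covs, K = 3)
  full_model <- filter_age_correlated_factors(full_model, sim$covs$age)
  full <- call_age_genes(age_scan(pre, sim$covs,
                                  factors = kept_factor_scores(full_model)))
  sub <- subsample_robustness(pre, sim$covs, n_target = 40, reps = 1,
                              seed = 1, K = 3)
  expect_identical(sub$total, attr(full, "counts")$total)

  s1 <- subsample_robustness(pre, sim$covs, n_target = 30, reps = 2,
                             seed = 99, K = 3)
  s2 <- subsample_robustness(pre, sim$covs, n_target = 30, reps = 2,
                             seed = 99, K = 3)
  expect_identical(s1, s2)

  expect_error(subsample_robustness(pre, sim$covs, n_target = 41), "exceeds")
})

test_that("power rises with sample size under subsampling", {
  cfg <- sim_config(frac_age_genes = 0.25, age_effect = 0.03,
                    frac_dv_genes = 0, n_interaction_pairs = 0,
                    n_confounders = 0)
  sim <- simulate_dataset(100, 200, 5, seed = 8, config = cfg)
  pre <- preprocess_expression(sim$expr)
  s54 <- subsample_robustness(pre, sim$covs, n_target = 54, reps = 6,
                              seed = 3, K = 0)
  s100 <- subsample_robustness(pre, sim$covs, n_target = 100, reps = 1,
                               seed = 3, K = 0)
  m54 <- attr(s54, "mean_counts")
  m100 <- attr(s100, "mean_counts")
  expect_lte(m54$total[m54$fdr == 0.05], m100$total[m100$fdr == 0.05])
})

test_that("cross-region concordance is a rank statistic with unit diagonal", {
  set.seed(10)
  p1 <- setNames(runif(300), sprintf("G%03d", 1:300))
  # a strictly monotone transform has identical ranks
  p2 <- p1^2
  scc <- cross_region_concordance(list(a = p1, b = p2, self = p1))
  expect_equal(diag(scc), c(a = 1, b = 1, self = 1))
  expect_equal(scc["a", "b"], 1)
  expect_equal(scc["a", "self"], 1)

  # independent vectors decorrelate
  hits <- replicate(50, {
    x <- setNames(runif(1000), 1:1000)
    y <- setNames(runif(1000), 1:1000)
    abs(cross_region_concordance(list(r1 = x, r2 = y))["r1", "r2"])
  })
  expect_gte(mean(hits < 0.11), 0.9)

  expect_error(cross_region_concordance(list(a = p1)), "2 regions")
  expect_error(cross_region_concordance(list(a = p1[1:5], b = p2[1:5])),
               "fewer than 10")
})
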