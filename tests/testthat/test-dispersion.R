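test_that("age-group assignment follows the boundary with size guards", {
  g <- assign_age_groups(c(45, 60, 61, 70), boundary = 60)
  expect_identical(as.character(g), c("young", "young", "old", "old"))

  expect_error(assign_age_groups(c(45, 60, 61, 70), boundary = 59),
               "young")
  expect_error(assign_age_groups(c(30, 40, 50), boundary = 60),
               "empty old")
  # the alternative split used for the TERF-style display
  g59 <- assign_age_groups(c(45, 50, 59, 60, 61, 70), boundary = 59)
  expect_identical(sum(g59 == "young"), 3L)
})

test_that("Levene's F matches the hand-derived worked example", {
  x <- c(0, 2, 4, 1, 2, 3)
  grp <- factor(rep(c("A", "B"), each = 3))
  lt <- levene_univariate(x, grp)
  # z_A = (2,0,2), z_B = (1,0,1): SSB = 2/3, SSW = 10/3 -> F = 0.8
  expect_equal(lt$F, 0.8, tolerance = 1e-12)
  expect_identical(lt$df, c(1L, 4L))
  expect_false(lt$degenerate)

  # identical groups: F = 0, P = 1
  same <- levene_univariate(c(1, 2, 3, 1, 2, 3), grp)
  expect_equal(same$F, 0)
  expect_equal(same$pvalue, 1)
})

test_that("two-group Levene equals the squared pooled t on deviations", {
  set.seed(12)
  x <- rnorm(30)
  grp <- factor(rep(c("young", "old"), each = 15), levels = c("young", "old"))
  lt <- levene_univariate(x, grp)
  z <- abs(x - ave(x, grp))
  tt <- t.test(z ~ grp, var.equal = TRUE)
  expect_equal(lt$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(lt$pvalue, tt$p.value, tolerance = 1e-10)
})

test_that("Levene agrees with the car implementation (mean and median centers)", {
  skip_if_not_installed("car")
  set.seed(13)
  x <- rnorm(45, sd = rep(c(1, 2, 3), each = 15))
  grp <- factor(rep(c("a", "b", "c"), each = 15))
  ours <- levene_univariate(x, grp, center = "mean")
  ref <- car::leveneTest(x, grp, center = mean)
  expect_equal(ours$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(ours$pvalue, ref$`Pr(>F)`[1], tolerance = 1e-10)

  bf <- levene_univariate(x, grp, center = "median")
  ref_bf <- car::leveneTest(x, grp, center = median)
  expect_equal(bf$F, ref_bf$`F value`[1], tolerance = 1e-10)
})

test_that("dv_scan detects planted variance shifts and handles degenerates", {
  set.seed(14)
  n <- 80
  ages <- c(rep(30, 40), rep(65, 40))
  grp <- assign_age_groups(ages)
  vals <- rbind(
    planted = c(rnorm(40, sd = 1), rnorm(40, sd = 3)),
    flat = rep(1, n),
    t(replicate(100, rnorm(n)))
  )
  rownames(vals) <- c("planted", "flat", sprintf("null%03d", 1:100))
  colnames(vals) <- sprintf("S%03d", 1:n)
  em <- expression_matrix(vals, state = "residual")
  out <- dv_scan(em, grp)

  planted <- out[out$unit_id == "planted", ]
  expect_true(planted$significant)
  expect_identical(planted$direction, "increase")

  flat <- out[out$unit_id == "flat", ]
  expect_true(flat$degenerate)
  expect_true(is.na(flat$adjusted))   # excluded from the BH pool

  # null genes: essentially no rejections at FDR 5%
  nulls <- out[grepl("null", out$unit_id), ]
  expect_lte(sum(nulls$significant), 2L)
})

test_that("MCD with h = n is the classical estimate and C-steps never increase the determinant", {
  set.seed(15)
  X <- matrix(rnorm(60), 30, 2)
  fit <- mcd_estimate(X, h = 30)
  expect_equal(fit$center, colMeans(X))
  expect_equal(fit$scatter, cov(X))
  expect_equal(fit$distances, sqrt(mahalanobis(X, colMeans(X), cov(X))))

  Y <- rbind(matrix(rnorm(180, 0, 0.5), 90, 2),
             matrix(rnorm(20, 8, 0.5), 10, 2))
  rob <- mcd_estimate(Y, h = 75, seed = 2)
  expect_true(all(diff(rob$det_history) <= 1e-12))
  expect_gt(min(rob$distances[91:100]), max(rob$distances[1:90]))

  expect_error(mcd_estimate(X, h = 5), "h must lie")
  expect_error(mcd_estimate(matrix(rnorm(4), 2, 2)), "more samples")
})

test_that("MCD agrees with an independent robust estimator on contaminated data", {
  skip_if_not_installed("MASS")
  set.seed(16)
  X <- rbind(matrix(rnorm(160, 0, 1), 80, 2),
             matrix(rnorm(40, 10, 1), 20, 2))
  ours <- mcd_estimate(X, h = 75, seed = 3)
  ref <- MASS::cov.rob(X, method = "mcd", quantile.used = 75)
  # both should locate the inlier cluster (true center 0)
  expect_lt(max(abs(ours$center)), 0.5)
  expect_lt(max(abs(ours$center - ref$center)), 0.5)
  # and rank the planted outliers above all inliers
  expect_gt(min(ours$distances[81:100]), max(ours$distances[1:80]))
})

test_that("robust Mahalanobis distance has the Euclidean special case", {
  model <- structure(list(center = c(0, 0), scatter = diag(2), h = 4L),
                     class = "mcd_fit")
  expect_equal(robust_md(matrix(c(3, 4), 1, 2), model), 5)
  expect_equal(robust_md(matrix(c(0, 0), 1, 2), model), 0)

  bad <- structure(list(center = c(0, 0),
                        scatter = matrix(c(1, 1, 1, 1), 2, 2), h = 4L),
                   class = "mcd_fit")
  expect_error(robust_md(matrix(1, 1, 2), bad), "positive definite")
  expect_error(robust_md(matrix(1, 1, 3), model), "columns")
})

test_that("classical-estimator distances and multivariate F are affine invariant", {
  set.seed(17)
  X <- matrix(rnorm(120), 40, 3)
  grp <- factor(rep(c("young", "old"), each = 20), levels = c("young", "old"))
  A <- matrix(c(2, 0.5, 0, -1, 3, 0.2, 0.3, 0, 1.5), 3, 3)
  b <- c(10, -5, 2)
  XT <- sweep(X %*% t(A), 2, b, "+")

  m1 <- mcd_estimate(X, h = 40)
  m2 <- mcd_estimate(XT, h = 40)
  expect_equal(m1$distances, m2$distances, tolerance = 1e-8)

  f1 <- levene_multivariate(X, grp, estimator = "classical")
  f2 <- levene_multivariate(XT, grp, estimator = "classical")
  expect_equal(f1$F, f2$F, tolerance = 1e-8)
})

test_that("multivariate Levene degenerates to zero F for identical group point sets", {
  set.seed(18)
  half <- matrix(rnorm(24), 12, 2)
  X <- rbind(half, half)
  grp <- factor(rep(c("young", "old"), each = 12),
                levels = c("young", "old"))
  lt <- levene_multivariate(X, grp, estimator = "classical")
  expect_equal(lt$F, 0)
  expect_equal(lt$pvalue, 1)
})

test_that("single-gene multivariate test tracks the univariate one", {
  set.seed(19)
  ratios <- replicate(50, {
    x <- c(rnorm(20, sd = 1), rnorm(20, sd = 2))
    grp <- factor(rep(c("young", "old"), each = 20),
                  levels = c("young", "old"))
    pm <- levene_multivariate(matrix(x, ncol = 1), grp,
                              estimator = "classical")$pvalue
    pu <- levene_univariate(x, grp)$pvalue
    pm / pu
  })
  # same evidence up to the centering convention
  expect_gt(mean(ratios > 0.5 & ratios < 2), 0.7)
})

test_that("gene-set scan finds the planted dispersed set and skips tiny sets", {
  set.seed(20)
  n <- 60
  ages <- c(rep(35, 40), rep(65, 20))
  grp <- assign_age_groups(ages)
  vals <- t(replicate(30, rnorm(n)))
  vals[1, ] <- c(rnorm(40, sd = 0.5), rnorm(20, sd = 1.5))
  vals[2, ] <- c(rnorm(40, sd = 0.5), rnorm(20, sd = 1.5))
  dimnames(vals) <- list(sprintf("G%02d", 1:30), sprintf("S%02d", 1:n))
  em <- expression_matrix(vals, state = "residual")
  sets <- gene_set_collection(list(
    PLANTED = c("G01", "G02"),
    NULL1 = c("G03", "G04"), NULL2 = c("G05", "G06"),
    TINY = c("G07", "NOT_PRESENT")))
  expect_message(out <- dv_geneset_scan(em, sets, grp, seed = 1), "skipped")
  expect_identical(out$unit_id[1], "PLANTED")
  expect_identical(out$direction[1], "increase")
  expect_identical(names(attr(out, "skipped")), "TINY")
})
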