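# Cross-validation plan, standardized ridge-logistic model, Monte-Carlo
# Shapley attribution, and ranking-stability aggregation.

test_that("cv plan is stratified, disjoint, exhaustive and deterministic", {
  y <- rep(c(1, 0), c(15, 45))
  plan <- make_cv_plan(y, k = 5, repeats = 30, base_seed = 3)
  expect_length(plan$splits, 150)
  for (sp in plan$splits[1:25]) {
    expect_length(intersect(sp$train, sp$test), 0)
    expect_equal(sum(y[sp$test]), 3)          # 15 fallers / 5 folds
    expect_length(sp$test, 12)
  }
  # test folds within one repeat partition all subjects
  r1 <- plan$splits[vapply(plan$splits, `[[`, 1, "repeat_id") == 1]
  expect_setequal(unlist(lapply(r1, `[[`, "test")), seq_along(y))
  plan2 <- make_cv_plan(y, k = 5, repeats = 30, base_seed = 3)
  expect_identical(plan$splits, plan2$splits)
  expect_error(make_cv_plan(rep(c(1, 0), c(3, 40)), k = 5), "fewer than k")
})

test_that("standardization uses training statistics only", {
  set.seed(1)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(0, 1), 10)
  fit <- fit_standardized_logistic(x, y)
  xs <- std_transform(fit, x)
  expect_equal(xs[, 1], (x[, 1] - mean(x[, 1])) / sd(x[, 1]))
  # an extreme test-fold outlier must transform with train stats untouched
  out <- matrix(c(1e6, 1e6), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(as.numeric(std_transform(fit, out)),
               as.numeric((c(1e6, 1e6) - fit$center) / fit$scale))
  expect_identical(fit$center, c(a = mean(x[, 1]), b = mean(x[, 2])))
})

test_that("constant features are dropped and one-class folds rejected", {
  set.seed(2)
  x <- cbind(const = rep(1, 20), real = rnorm(20))
  y <- rep(c(0, 1), 10)
  expect_warning(fit <- fit_standardized_logistic(x, y), "constant")
  expect_identical(unname(fit$keep), 2L)
  expect_error(fit_standardized_logistic(x, rep(1, 20)), "single class")
})

test_that("a duplicated column splits its ridge weight symmetrically", {
  set.seed(3)
  a <- rnorm(30)
  y <- as.integer(a + rnorm(30, 0, 0.5) > 0)
  x <- matrix(a, 30, 1, dimnames = list(NULL, "a"))
  xd <- cbind(x, a2 = a)
  fit_d <- fit_standardized_logistic(xd, y, lambda = 1)
  expect_equal(unname(fit_d$beta[1]), unname(fit_d$beta[2]), tolerance = 1e-8)
  # duplicating the sole predictor at penalty lambda is exactly equivalent to
  # the single column at lambda/2 (the split halves the effective penalty)
  fit_h <- fit_standardized_logistic(x, y, lambda = 0.5)
  expect_equal(predict(fit_d, xd), predict(fit_h, x), tolerance = 1e-6)
})

test_that("Monte-Carlo Shapley matches the additive closed form on the link scale", {
  set.seed(4)
  n <- 30; p <- 6
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- as.integer(plogis(x[, 1] - 0.8 * x[, 2]) > runif(n))
  fit <- fit_standardized_logistic(x, y, lambda = 1)
  sh <- mc_shapley(fit, x, n_sim = 128, seed = 5, scale = "link")
  # exact Shapley of an additive model: beta_j^std * (z_j - mean background z_j)
  z <- std_transform(fit, x)
  exact <- sweep(sweep(z, 2, colMeans(z)), 2, fit$beta, "*")
  # 180 simultaneous MC estimates: essentially all within 3 SE, none beyond 5
  zdev <- abs(sh$shap - exact) / (sh$se + 1e-12)
  expect_gte(mean(zdev <= 3), 0.99)
  expect_true(all(zdev <= 5))
  # a constant model attributes nothing
  fit0 <- fit
  fit0$beta <- rep(0, length(fit0$beta))
  sh0 <- mc_shapley(fit0, x, n_sim = 8, seed = 6)
  expect_true(all(sh0$shap == 0))
  expect_error(mc_shapley(fit, x, n_sim = 0), "n_sim")
})

test_that("Monte-Carlo error shrinks like 1/sqrt(n_sim)", {
  set.seed(8)
  n <- 20
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.integer(x[, 1] > 0)
  fit <- fit_standardized_logistic(x, y)
  est <- function(ns) vapply(1:12, function(s)
    mc_shapley(fit, x[1:2, , drop = FALSE], background = x, n_sim = ns,
               seed = s)$shap[1, 1], numeric(1))
  ratio <- sd(est(8)) / sd(est(80))
  expect_gt(ratio, 1.7)                 # sqrt(10) ~ 3.2, generous band
  expect_lt(ratio, 6)
})

test_that("condition analysis: exact top-5 accounting and determinism", {
  pl <- make_planted_features(12, 24, p = 12, effect = 0, seed = 10)
  plan <- make_cv_plan(pl$y, k = 4, repeats = 3, base_seed = 2)
  res <- run_condition_analysis(pl$X, pl$y, plan, n_sim = 16)
  expect_equal(sum(res$stability$top5_prop), 5, tolerance = 1e-12)
  expect_true(all(res$stability$top5_prop >= 0 & res$stability$top5_prop <= 1))
  expect_equal(res$n_splits, 12)
  res2 <- run_condition_analysis(pl$X, pl$y, plan, n_sim = 16)
  expect_identical(res$stability, res2$stability)
  expect_identical(res$oof, res2$oof)
})

test_that("a strongly planted feature dominates the top-5 ranking", {
  pl <- make_planted_features(15, 45, p = 10, effect = 1.5, feature = 3,
                              seed = 11)
  plan <- make_cv_plan(pl$y, k = 5, repeats = 4, base_seed = 4)
  res <- run_condition_analysis(pl$X, pl$y, plan, n_sim = 32)
  planted <- cop_feature_names()[3]
  expect_gte(res$stability$top5_prop[res$stability$feature == planted], 0.9)
  expect_gt(res$oof["auroc"], 0.6)
})
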