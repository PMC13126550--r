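test_that("importance ranking is normalised and finds a perfect predictor", {
  set.seed(2)
  n <- 300
  y <- factor(rep(c("normal", "dementia"), each = n / 2),
              levels = c("normal", "dementia"))
  x <- cbind(signal = as.numeric(y == "dementia"),
             noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  rk <- rank_importance(x, y, num_trees = 100, seed = 3)
  expect_equal(sum(rk$importance), 1, tolerance = 1e-9)
  expect_equal(rk$variable[1], "signal")
  expect_gt(rk$importance[1], 0.5)
  rk2 <- rank_importance(x, y, num_trees = 100, seed = 3)
  expect_identical(rk$importance, rk2$importance)
})

test_that("identical noise predictors receive approximately uniform importance", {
  spreads <- vapply(1:3, function(s) {
    set.seed(100 + s)
    n <- 400
    x <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("v", 1:6)))
    y <- factor(sample(c("a", "b"), n, replace = TRUE))
    rk <- rank_importance(x, y, num_trees = 300, seed = s)
    max(rk$importance) - min(rk$importance)
  }, numeric(1))
  expect_lt(mean(spreads), 0.08)  # uniform would be 1/6 each
})

test_that("stump-forest importance equals the hand-computed Gini decrease", {
  x <- cbind(a = c(rep(0, 20), rep(1, 20)), b = 0)
  y <- factor(c(rep("d", 2), rep("n", 18), rep("d", 16), rep("n", 4)),
              levels = c("n", "d"))
  f <- ranger::ranger(y = y, x = data.frame(x), num.trees = 1, mtry = 2,
                      max.depth = 1, replace = FALSE, sample.fraction = 1,
                      importance = "impurity", seed = 1, num.threads = 1)
  # the only split separates a = 0 (2 d, 18 n) from a = 1 (16 d, 4 n)
  hand <- 40 * gini_impurity(c(18, 22)) -
    20 * gini_impurity(c(2, 18)) - 20 * gini_impurity(c(16, 4))
  expect_equal(unname(f$variable.importance["a"]), hand, tolerance = 1e-9)
  expect_equal(unname(f$variable.importance["b"]), 0)
})

test_that("out-of-bag error equals hand-rolled vote counting on small forests", {
  set.seed(8)
  for (rep in 1:4) {
    n <- 50
    x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("p", "q", "r")))
    y <- factor(ifelse(x[, 1] + rnorm(n, 0, 0.8) > 0, "b", "a"))
    f <- balanced_rf(x, y, num_trees = 5, seed = rep)
    expect_equal(oob_error(f, x, y), oracle_oob(f, x, y), tolerance = 1e-12)
  }
})

test_that("stepwise OOB curve is deterministic with valid errors", {
  set.seed(5)
  n <- 200
  x <- cbind(s1 = rnorm(n), s2 = rnorm(n), n1 = rnorm(n), n2 = rnorm(n))
  y <- factor(ifelse(x[, 1] + 0.8 * x[, 2] + rnorm(n, 0, 0.7) > 0, "b", "a"))
  attr(x, "variable") <- colnames(x)
  rk <- rank_importance(x, y, num_trees = 60, seed = 1)
  c1 <- oob_stepwise(x, y, rk, cv_folds = 3, repetitions = 2, num_trees = 40,
                     seed = 6)
  c2 <- oob_stepwise(x, y, rk, cv_folds = 3, repetitions = 2, num_trees = 40,
                     seed = 6)
  expect_identical(attr(c1, "errors"), attr(c2, "errors"))
  expect_true(all(c1$mean_oob_error >= 0 & c1$mean_oob_error <= 1))
  expect_true(all(c1$sd_oob_error >= 0))
  expect_equal(attr(c1, "selected_m"), which.min(c1$mean_oob_error))
  expect_equal(length(attr(c1, "selected_variables")),
               attr(c1, "selected_m"))
})

test_that("univariable logistic odds ratio equals the 2x2 cross-product ratio", {
  tab <- expand.grid(y = c(1, 0), x = c("yes", "no"))
  counts <- c(40, 60, 15, 85)
  d <- tab[rep(1:4, counts), ]
  names(d) <- c("outcome", "exposed")
  cb <- structure(list(exposed = list(type = "binary",
                                      levels = c("no", "yes"),
                                      reference = "no")),
                  class = "cogstatus_codebook")
  fit <- fit_multivariable_logistic(d, "exposed", cb)
  expect_equal(fit$odds_ratio, (40 * 85) / (15 * 60), tolerance = 1e-6)
})

test_that("null logistic model intercept equals the log-odds of prevalence", {
  d <- data.frame(outcome = rep(c(1, 0), c(96, 904)))
  fit <- stats::glm(outcome ~ 1, data = d, family = stats::binomial())
  expect_equal(unname(stats::coef(fit)), stats::qlogis(0.096),
               tolerance = 1e-8)
})

test_that("perfect separation is detected and reported", {
  d <- data.frame(outcome = rep(c(1, 0), each = 50),
                  sep = rep(c("yes", "no"), each = 50))
  cb <- structure(list(sep = list(type = "binary", levels = c("no", "yes"),
                                  reference = "no")),
                  class = "cogstatus_codebook")
  expect_error(fit_multivariable_logistic(d, "sep", cb), "separation")
})

test_that("significance selection keeps whole factors and preserves order", {
  fake <- structure(
    data.frame(variable = c("a", "b", "b", "c"),
               level = c("yes", "l2", "l3", "yes"),
               coef = 0, se = 1, odds_ratio = 1, ci_low = 0.5, ci_high = 2,
               p_value = c(0.5, 0.049, 0.70, 0.51)),
    class = c("logistic_result", "data.frame"),
    variables = c("c", "b", "a"))
  expect_equal(select_significant(fake), "b")
  fake$p_value <- rep(0.5, 4)
  expect_equal(length(select_significant(fake)), 0)
  fake$p_value <- c(0.01, 0.9, 0.9, 0.02)
  expect_equal(select_significant(fake), c("c", "a"))  # ranking order kept
})

test_that("planted-effect coefficients are recovered within Wald intervals", {
  effects <- list(depressive_symptoms = 1.2, retinopathy = 0.8)
  cfg <- cohort_config(n_participants = 6000, impairment_fraction = 0,
                       latent_effects = effects, seed = 77)
  co <- generate_cohort(cfg, items = FALSE)
  co$outcome <- as.integer(co$true_status == "dementia")
  fit <- fit_multivariable_logistic(co, names(effects))
  truth <- c(depressive_symptoms = 1.2, retinopathy = 0.8)
  for (i in seq_len(nrow(fit))) {
    b <- truth[fit$variable[i]]
    expect_lt(abs(fit$coef[i] - b), 3.5 * fit$se[i])
  }
})

test_that("retraining restricts to the selected columns and fits separable data", {
  set.seed(9)
  n <- 120
  x <- cbind(keepme = c(rep(0, 60), rep(1, 60)), drop1 = rnorm(n),
             drop2 = rnorm(n))
  attr(x, "variable") <- colnames(x)
  d <- data.frame(keepme = x[, 1],
                  outcome = as.integer(x[, 1] == 1))
  cb <- structure(list(keepme = list(type = "numeric")),
                  class = "cogstatus_codebook")
  # logistic on separable data errors; use a noisy outcome for the lr part
  d$outcome[c(1, 61)] <- 1 - d$outcome[c(1, 61)]
  final <- retrain_final(x, d, "keepme", cb, num_trees = 50, seed = 4)
  expect_equal(final$columns, "keepme")
  expect_equal(final$rf$num.independent.variables, 1)
  preds <- predict(final$rf, data.frame(keepme = x[, 1]),
                   num.threads = 1)$predictions[, "dementia"]
  acc <- mean((preds >= 0.5) == (d$outcome == 1))
  expect_gt(acc, 0.9)
  f2 <- retrain_final(x, d, "keepme", cb, num_trees = 50, seed = 4)
  p2 <- predict(f2$rf, data.frame(keepme = x[, 1]),
                num.threads = 1)$predictions[, "dementia"]
  expect_identical(preds, p2)
})
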