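test_that("confusion metrics satisfy their defining identities", {
  perfect <- confusion_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$g_mean, 1)
  expect_equal(perfect$accuracy, 1)
  allneg <- confusion_metrics(c(1, 0, 0, 1), c(0, 0, 0, 0))
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$specificity, 1)
  expect_equal(allneg$g_mean, 0)
  expect_true(is.na(allneg$precision))
  set.seed(14)
  for (rep in 1:10) {
    l <- rbinom(50, 1, 0.3); l[1] <- 1; l[2] <- 0
    p <- rbinom(50, 1, 0.4)
    cm <- confusion_metrics(l, p)
    expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 50)
    expect_equal(cm$g_mean, sqrt(cm$sensitivity * cm$specificity),
                 tolerance = 1e-12)
    if (!is.na(cm$f1)) {
      expect_equal(cm$f1, 2 * cm$precision * cm$sensitivity /
                     (cm$precision + cm$sensitivity), tolerance = 1e-12)
    }
  }
  expect_error(confusion_metrics(c(1, 0), c(1, 0, 1)), "length")
})

test_that("ROC area equals exhaustive pairwise concordance on small sets", {
  set.seed(6)
  for (rep in 1:12) {
    n <- sample(4:12, 1)
    l <- rbinom(n, 1, 0.5)
    l[1] <- 1; l[2] <- 0
    s <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # forces ties
    got <- roc_pr_curves(l, s)$auc_roc
    expect_equal(got, oracle_auc(l, s), tolerance = 1e-12)
  }
  ident <- roc_pr_curves(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(ident$auc_roc, 1)
  expect_equal(ident$pr_auc, 1)
  expect_error(roc_pr_curves(c(1, 1), c(0.2, 0.4)), "both classes")
})

test_that("null scores give chance-level AUC and prevalence-level PR-AUC", {
  set.seed(10)
  n <- 4000
  l <- rbinom(n, 1, 0.15)
  s <- runif(n)
  r <- roc_pr_curves(l, s)
  expect_lt(abs(r$auc_roc - 0.5), 0.03)
  expect_lt(abs(r$pr_auc - mean(l)), 0.03)
})

test_that("stratified bootstrap intervals are ordered, contain the estimate, and collapse under perfect separation", {
  set.seed(11)
  l <- rbinom(300, 1, 0.2); l[1] <- 1; l[2] <- 0
  s <- l * 0.5 + runif(300) * 0.8
  auc_fn <- function(ll, ss) roc_pr_curves(ll, ss)$auc_roc
  ci <- bootstrap_ci(auc_fn, l, s, reps = 300, seed = 2)
  pt <- auc_fn(l, s)
  expect_lte(ci$lower, ci$upper)
  expect_gte(ci$upper, pt - 1e-9)
  expect_lte(ci$lower, pt + 1e-9)
  expect_true(ci$lower >= 0 && ci$upper <= 1)
  ci2 <- bootstrap_ci(auc_fn, l, s, reps = 300, seed = 2)
  expect_identical(ci, ci2)
  sep <- bootstrap_ci(auc_fn, l, as.numeric(l), reps = 150, seed = 3)
  expect_equal(sep$lower, 1)
  expect_equal(sep$upper, 1)
  expect_error(bootstrap_ci(auc_fn, l, s, reps = 50), "100")
})

test_that("threshold policies behave as documented", {
  expect_equal(choose_threshold(c(1, 0), c(0.9, 0.1), "fixed_0.5"), 0.5)
  # perfectly separated scores: midpoint of the gap
  l <- c(0, 0, 1, 1)
  s <- c(0.1, 0.2, 0.8, 0.9)
  expect_equal(choose_threshold(l, s, "gmean_max"), 0.5)
  # brute force equivalence on a noisy set
  set.seed(12)
  l2 <- rbinom(60, 1, 0.4); l2[1] <- 1; l2[2] <- 0
  s2 <- l2 * 0.4 + runif(60) * 0.9
  th <- choose_threshold(l2, s2, "gmean_max")
  gmean_at <- function(t) {
    p <- as.integer(s2 >= t)
    sqrt(mean(p[l2 == 1] == 1) * mean(p[l2 == 0] == 0))
  }
  cand <- c(min(s2) - 1e-6, sort(s2) + 1e-9)
  expect_gte(gmean_at(th) + 1e-12, max(vapply(cand, gmean_at, numeric(1))))
  expect_error(choose_threshold(l2, s2, "weird"), "arg")
})

test_that("evaluation report keeps its internal identities", {
  set.seed(13)
  l <- rbinom(400, 1, 0.2); l[1] <- 1; l[2] <- 0
  s <- plogis(qlogis(0.2) + 2 * l + rnorm(400))
  ev <- evaluate_scores(l, s, threshold = 0.5, boot_reps = 150, seed = 9)
  expect_equal(ev$g_mean, sqrt(ev$sensitivity * ev$specificity),
               tolerance = 1e-12)
  expect_equal(ev$tp + ev$fp + ev$tn + ev$fn, 400)
  expect_true(ev$auc_roc_ci[1] <= ev$auc_roc & ev$auc_roc <= ev$auc_roc_ci[2])
  expect_true(ev$pr_auc_ci[1] <= ev$pr_auc & ev$pr_auc <= ev$pr_auc_ci[2])
})

test_that("forests beat the additive logistic model on interaction-driven outcomes", {
  # planted non-additive (XOR-like) structure; the RF/LR ordering should hold
  # for a clear majority of seeds
  wins <- vapply(1:9, function(s) {
    set.seed(400 + s)
    n <- 600
    a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
    eta <- -2.2 + 3 * as.numeric(xor(a, b))
    y <- rbinom(n, 1, plogis(eta))
    if (length(unique(y)) < 2) return(NA)
    tr <- seq_len(n) <= 400
    x <- cbind(a = a, b = b, c = rnorm(n))
    yf <- factor(ifelse(y == 1, "dementia", "normal"),
                 levels = c("normal", "dementia"))
    rf <- balanced_rf(x[tr, ], yf[tr], num_trees = 150, seed = s,
                      probability = TRUE)
    rf_s <- predict(rf, data.frame(x[!tr, ]),
                    num.threads = 1)$predictions[, "dementia"]
    lr <- stats::glm(y ~ a + b + c, data = data.frame(x, y = y)[tr, ],
                     family = stats::binomial())
    lr_s <- predict(lr, newdata = data.frame(x[!tr, ]), type = "response")
    auc <- function(sc) roc_pr_curves(y[!tr], sc)$auc_roc
    auc(rf_s) > auc(lr_s)
  }, logical(1))
  expect_gte(sum(wins, na.rm = TRUE), 7)
})

test_that("full pipeline runs are reproducible end to end", {
  cfg <- cohort_config(n_participants = 900, seed = 55)
  args <- list(config = cfg, seed = 55, k_grid = 1:4, elbow_repetitions = 2,
               elbow_rows = 250, cv_folds = 3, cv_repetitions = 1,
               num_trees = 60, boot_reps = 120)
  # sparse age cells at this cohort size produce expected quasi-separation
  # warnings from the logistic stage
  r1 <- suppressWarnings(do.call(run_pipeline, args))
  r2 <- suppressWarnings(do.call(run_pipeline, args))
  expect_identical(unclass(r1$eval_rf), unclass(r2$eval_rf))
  expect_identical(unclass(r1$eval_lr), unclass(r2$eval_lr))
  expect_identical(r1$significant, r2$significant)
  # run directory artifacts
  out <- file.path(tempdir(), "cogstatus-run-test")
  unlink(out, recursive = TRUE)
  r3 <- suppressWarnings(do.call(run_pipeline, c(args, list(out_dir = out))))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(file.exists(file.path(out, "odds_ratios.csv")))
  expect_true(file.exists(file.path(out, "eval_rf.json")))
})

test_that("ROC area agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  l <- rbinom(200, 1, 0.3); l[1] <- 1; l[2] <- 0
  s <- plogis(l + rnorm(200))
  ours <- roc_pr_curves(l, s)$auc_roc
  theirs <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})
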