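#' Run the full analysis pipeline on a (synthetic or supplied) cohort
#'
#' Orchestrates every stage: cohort generation (or ingestion), instrument
#' scoring, regression-based norming and status derivation, binary dataset
#' construction, stratified train/test split, fit-on-train rescaling and KNN
#' imputation with elbow-selected k, balanced random-forest importance
#' ranking, stepwise OOB-error variable selection under repeated stratified
#' cross-validation, multivariable logistic modelling with odds ratios,
#' retraining of both final models on the significant subset, and
#' imbalance-aware evaluation of both on the held-out test partition.
#'
#' The decision threshold is chosen on training scores only (out-of-bag
#' probabilities for the forest, fitted probabilities for the logistic model)
#' under the configured policy.
#'
#' @param config a [cohort_config()]; ignored when `cohort` is supplied.
#' @param cohort optional pre-built cohort data.frame.
#' @param seed master seed; every stage derives its own stream from it.
#' @param test_fraction held-out fraction (default 0.20).
#' @param k_grid,elbow_repetitions,elbow_rows elbow-method settings:
#'   candidate k values, repetitions, and a cap on the number of complete
#'   training rows used (keeps the distance matrices small; `NULL` = all).
#' @param cv_folds,cv_repetitions stepwise OOB cross-validation settings.
#' @param num_trees trees per forest.
#' @param threshold_policy passed to [choose_threshold()].
#' @param boot_reps bootstrap replicates for evaluation CIs.
#' @param alpha significance level for variable retention.
#' @param out_dir optional directory; when given, JSON/CSV artifacts and a
#'   provenance manifest are written there.
#' @return list of class `cogstatus_run` with elements `status_report`,
#'   `norm_model`, `binary_report`, `imputation`, `ranking`, `oob_curve`,
#'   `logistic`, `significant`, `final`, `eval_rf`, `eval_lr`, `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), cohort = NULL, seed = 1,
                         test_fraction = 0.20, k_grid = 1:20,
                         elbow_repetitions = 30, elbow_rows = 2000,
                         cv_folds = 10, cv_repetitions = 30, num_trees = 500,
                         threshold_policy = "gmean_max", boot_reps = 2000,
                         alpha = 0.05, out_dir = NULL) {
  codebook <- default_codebook()
  if (is.null(cohort)) {
    cohort <- generate_cohort(config, seed = child_seed(seed, 1))
  }
  scored <- score_cohort(cohort, codebook)
  derived <- derive_status(scored)
  binary <- build_binary_dataset(derived$cohort)

  sp <- split_train_test(binary$data, test_fraction,
                         seed = child_seed(seed, 2))
  pre <- preprocess_elbow_capped(sp$train, sp$test, codebook, k_grid,
                                 elbow_repetitions, elbow_rows,
                                 seed = child_seed(seed, 3))
  ytr <- factor(ifelse(sp$train$outcome == 1, "dementia", "normal"),
                levels = c("normal", "dementia"))
  yte <- sp$test$outcome

  ranking <- rank_importance(pre$train_matrix, ytr, num_trees = num_trees,
                             seed = child_seed(seed, 4))
  curve <- oob_stepwise(pre$train_matrix, ytr, ranking, cv_folds = cv_folds,
                        repetitions = cv_repetitions, num_trees = num_trees,
                        seed = child_seed(seed, 5))
  sel_vars <- attr(curve, "selected_variables")
  train_lr <- pre$train
  train_lr$outcome <- sp$train$outcome
  lr_fit <- fit_multivariable_logistic(train_lr, sel_vars, codebook,
                                       on_separation = "warn")
  signif_vars <- select_significant(lr_fit, alpha)
  if (!length(signif_vars)) signif_vars <- sel_vars[1]
  final <- retrain_final(pre$train_matrix, train_lr, signif_vars, codebook,
                         num_trees = num_trees, seed = child_seed(seed, 6),
                         on_separation = "warn")

  # training scores for threshold choice: OOB probabilities for the forest,
  # fitted probabilities for the logistic model
  rf_train_scores <- final$rf$predictions[, "dementia"]
  ok <- !is.na(rf_train_scores)
  rf_threshold <- choose_threshold(sp$train$outcome[ok], rf_train_scores[ok],
                                   threshold_policy)
  lr_train_scores <- stats::fitted(attr(final$lr, "fit"))
  lr_threshold <- choose_threshold(sp$train$outcome, lr_train_scores,
                                   threshold_policy)

  keep <- attr(pre$test_matrix, "variable") %in% signif_vars
  test_x <- data.frame(pre$test_matrix[, keep, drop = FALSE],
                       check.names = FALSE)
  rf_test_scores <- stats::predict(final$rf, data = test_x,
                                   num.threads = 1)$predictions[, "dementia"]
  test_lr <- pre$test
  test_lr$outcome <- yte
  lr_test_scores <- stats::predict(attr(final$lr, "fit"),
                                   newdata = lr_newdata(test_lr, signif_vars,
                                                        codebook),
                                   type = "response")

  eval_rf <- evaluate_scores(yte, rf_test_scores, rf_threshold,
                             boot_reps = boot_reps,
                             seed = child_seed(seed, 7))
  eval_lr <- evaluate_scores(yte, lr_test_scores, lr_threshold,
                             boot_reps = boot_reps,
                             seed = child_seed(seed, 8))

  manifest <- list(
    seed = seed, n_cohort = nrow(cohort), test_fraction = test_fraction,
    chosen_k = pre$k, cv_folds = cv_folds, cv_repetitions = cv_repetitions,
    num_trees = num_trees, threshold_policy = threshold_policy,
    boot_reps = boot_reps, alpha = alpha,
    selected_m = attr(curve, "selected_m"),
    significant_variables = signif_vars,
    package_version = as.character(utils::packageVersion("cogstatus"))
  )
  run <- structure(list(
    status_report = table(derived$cohort$status, useNA = "ifany"),
    norm_model = derived$norm_model,
    binary_report = binary$report,
    imputation = pre$report, chosen_k = pre$k,
    ranking = ranking, oob_curve = curve,
    logistic = lr_fit, significant = signif_vars, final = final,
    rf_threshold = rf_threshold, lr_threshold = lr_threshold,
    eval_rf = eval_rf, eval_lr = eval_lr, manifest = manifest
  ), class = "cogstatus_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# rebuild newdata with the factor/reference coding the logistic fit used
lr_newdata <- function(data, variables, codebook) {
  d <- data.frame(row.names = seq_len(nrow(data)))
  for (v in variables) {
    entry <- codebook[[v]]
    if (!is.null(entry) && entry$type != "numeric") {
      f <- codebook_factor(data[[v]], entry, v)
      d[[v]] <- stats::relevel(f, ref = entry$reference)
    } else {
      d[[v]] <- as.numeric(data[[v]])
    }
  }
  d
}

# elbow selection on a capped number of complete training rows (the distance
# matrix is quadratic in rows); imputation still uses the full partitions
preprocess_elbow_capped <- function(train, test, codebook, k_grid,
                                    repetitions, elbow_rows, seed) {
  scalers <- list()
  for (v in predictor_names(codebook)) {
    if (codebook[[v]]$type == "numeric" && isTRUE(codebook[[v]]$rescale)) {
      scalers[[v]] <- rescale_fit(as.numeric(train[[v]]))
    }
  }
  Xtr <- encode_features(train, codebook, scalers = scalers)
  Xte <- encode_features(test, codebook, scalers = scalers)
  complete <- which(stats::complete.cases(Xtr))
  sub <- if (!is.null(elbow_rows) && length(complete) > elbow_rows) {
    with_seed(child_seed(seed, 11), sample(complete, elbow_rows))
  } else complete
  report <- elbow_select_k(Xtr[sub, , drop = FALSE], k_grid = k_grid,
                           repetitions = repetitions,
                           seed = child_seed(seed, 12))
  k <- report$chosen_k
  tr_done <- if (any(is.na(Xtr))) knn_impute(Xtr, k) else Xtr
  te_done <- if (any(is.na(Xte))) knn_impute(Xte, k, reference = tr_done) else Xte
  for (m in c("tr_done", "te_done")) {
    tmp <- get(m)
    attr(tmp, "variable") <- attr(Xtr, "variable")
    attr(tmp, "codebook") <- attr(Xtr, "codebook")
    assign(m, tmp)
  }
  list(train = decode_features(tr_done), test = decode_features(te_done),
       report = report, k = k, scalers = scalers,
       train_matrix = tr_done, test_matrix = te_done)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  j <- function(x, f) jsonlite::write_json(x, file.path(out_dir, f),
                                           auto_unbox = TRUE, digits = NA,
                                           pretty = TRUE, force = TRUE)
  j(run$manifest, "manifest.json")
  j(unclass(run$norm_model), "norm_model.json")
  j(as.list(run$binary_report), "sample_flow.json")
  if (!is.null(run$imputation)) {
    j(run$imputation[c("k_grid", "mae_mean", "mae_sd", "chosen_k",
                       "repetitions", "removal_fraction", "rule")],
      "imputation_report.json")
  }
  utils::write.csv(as.data.frame(run$ranking),
                   file.path(out_dir, "importance_ranking.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(run$oob_curve),
                   file.path(out_dir, "oob_curve.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(run$logistic),
                   file.path(out_dir, "odds_ratios.csv"), row.names = FALSE)
  strip <- function(e) e[setdiff(names(e), character(0))]
  j(unclass(run$eval_rf), "eval_rf.json")
  j(unclass(run$eval_lr), "eval_lr.json")
  invisible(out_dir)
}

#' @export
print.cogstatus_run <- function(x, ...) {
  cat("Cognitive-status classification run\n")
  cat("  status counts:", paste(names(x$status_report), x$status_report,
                                collapse = ", "), "\n")
  cat(sprintf("  binary sample: %d retained of %d (%d impairment excluded)\n",
              x$binary_report["n_retained"], x$binary_report["n_input"],
              x$binary_report["n_excluded_impairment"]))
  cat(sprintf("  chosen k = %d; selected m = %d; significant variables: %s\n",
              x$chosen_k, attr(x$oob_curve, "selected_m"),
              paste(x$significant, collapse = ", ")))
  cat("  RF  test: "); print(x$eval_rf)
  cat("  LR  test: "); print(x$eval_lr)
  invisible(x)
}
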