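#' Fit a class-balanced random forest
#'
#' Wraps `ranger` with class weights inversely proportional to class
#' frequency, `w_c = n / (2 n_c)`, so misclassifying the minority (dementia)
#' class is penalised more heavily. Trees keep their in-bag record so
#' out-of-bag error can be recomputed by explicit vote counting.
#'
#' @param x numeric predictor matrix (encoded features).
#' @param y outcome factor (two classes).
#' @param num_trees number of trees (default 500).
#' @param mtry features per split (default `floor(sqrt(p))`).
#' @param seed RNG seed handed to the forest.
#' @param ... further `ranger` arguments.
#' @return a `ranger` fit.
#' @export
balanced_rf <- function(x, y, num_trees = 500, mtry = NULL, seed = NULL, ...) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop_cfg("balanced forest needs two outcome classes")
  tab <- table(y)
  cw <- as.numeric(sum(tab) / (length(tab) * tab))
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  d <- data.frame(..y = y, x, check.names = FALSE)
  ranger::ranger(dependent.variable.name = "..y", data = d,
                 num.trees = num_trees,
                 mtry = mtry %||% max(1, floor(sqrt(ncol(x)))),
                 class.weights = cw, keep.inbag = TRUE,
                 seed = seed, num.threads = 1, ...)
}

#' Out-of-bag error by explicit vote counting
#'
#' For every training record, aggregates the votes of the trees whose
#' bootstrap sample excluded it (majority vote; ties break to the first
#' outcome level) and reports 1 minus the out-of-bag accuracy. Records that
#' are in-bag in every tree are skipped.
#'
#' @param fit a `ranger` fit with `keep.inbag = TRUE`.
#' @param x predictor matrix the forest was trained on.
#' @param y outcome factor.
#' @return out-of-bag error in \[0, 1\].
#' @export
oob_error <- function(fit, x, y) {
  y <- droplevels(as.factor(y))
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  d <- data.frame(x, check.names = FALSE)
  per_tree <- stats::predict(fit, data = d, predict.all = TRUE,
                             num.threads = 1)$predictions
  inbag <- matrix(unlist(fit$inbag.counts), nrow = nrow(d))
  K <- nlevels(y)
  votes <- matrix(0L, nrow(d), K)
  oob <- inbag == 0
  for (cls in seq_len(K)) {
    votes[, cls] <- rowSums(oob & per_tree == cls)
  }
  has_oob <- rowSums(votes) > 0
  pred <- max.col(votes, ties.method = "first")
  mean(pred[has_oob] != as.integer(y)[has_oob])
}

#' Gini importance ranking of candidate predictors
#'
#' Trains a balanced forest on the encoded feature matrix and ranks the
#' predictors by total impurity (Gini) decrease, summed over all splits and
#' trees. Importance of a multi-column predictor (one-hot block) is the sum
#' over its columns. Importances are normalised to sum to 1; ties break by
#' codebook column order.
#'
#' @param x encoded feature matrix from [encode_features()] (carries the
#'   column-to-variable map).
#' @param y outcome factor.
#' @param num_trees,mtry,seed passed to [balanced_rf()].
#' @return object of class `importance_ranking`: data.frame with `variable`
#'   and `importance` (descending), plus attributes `forest_config` and
#'   `seed`.
#' @export
rank_importance <- function(x, y, num_trees = 500, mtry = NULL, seed = NULL) {
  if (ncol(x) < 2) stop_cfg("importance ranking needs at least 2 predictors")
  fit <- balanced_rf(x, y, num_trees = num_trees, mtry = mtry, seed = seed,
                     importance = "impurity")
  imp <- fit$variable.importance
  var_of <- attr(x, "variable") %||% colnames(x)
  agg <- tapply(imp, var_of, sum)
  agg <- agg[unique(var_of)]           # codebook column order
  total <- sum(agg)
  norm <- if (total > 0) agg / total else agg
  ord <- order(-norm, seq_along(norm)) # ties -> earlier codebook order
  out <- data.frame(variable = names(norm)[ord],
                    importance = as.numeric(norm[ord]),
                    raw_importance = as.numeric(agg[ord]),
                    stringsAsFactors = FALSE)
  structure(out, class = c("importance_ranking", "data.frame"),
            forest_config = list(num_trees = num_trees,
                                 mtry = mtry %||% max(1, floor(sqrt(ncol(x))))),
            seed = seed)
}

#' Stepwise out-of-bag error over nested importance prefixes
#'
#' Starting from the most important predictor, variables are added in ranking
#' order; for every nested subset a balanced forest is trained on each
#' training portion of a repeated stratified k-fold split and its out-of-bag
#' error recorded, giving `folds x repetitions` error estimates per subset
#' size. The selected size minimises the mean OOB error (ties to the smaller
#' subset).
#'
#' @param x encoded feature matrix (training partition).
#' @param y outcome factor.
#' @param ranking an `importance_ranking` (or character vector of variables in
#'   rank order).
#' @param cv_folds folds of the stratified split (default 10).
#' @param repetitions repeats of the fold split (default 30).
#' @param num_trees trees per forest (default 500).
#' @param seed RNG seed.
#' @param max_subset cap on the number of prefixes examined (default: all).
#' @return object of class `oob_curve`: data.frame with `m`, `variables`
#'   (comma-joined prefix), `mean_oob_error`, `sd_oob_error`; attributes
#'   `selected_m`, `selected_variables`, `errors` (matrix m x (folds*reps)).
#' @export
oob_stepwise <- function(x, y, ranking, cv_folds = 10, repetitions = 30,
                         num_trees = 500, seed = NULL, max_subset = NULL) {
  vars <- if (inherits(ranking, "data.frame")) ranking$variable else ranking
  var_of <- attr(x, "variable") %||% colnames(x)
  missing_vars <- setdiff(vars, var_of)
  if (length(missing_vars)) {
    stop_cfg("ranking names variables absent from the matrix: %s",
             paste(missing_vars, collapse = ", "))
  }
  y <- droplevels(as.factor(y))
  M <- length(vars)
  if (!is.null(max_subset)) M <- min(M, max_subset)
  n <- nrow(x)
  errs <- with_seed(seed, {
    folds_list <- lapply(seq_len(repetitions), function(r) {
      stratified_folds(y, cv_folds)
    })
    e <- matrix(NA_real_, M, cv_folds * repetitions)
    for (m in seq_len(M)) {
      keep <- var_of %in% vars[seq_len(m)]
      xm <- x[, keep, drop = FALSE]
      col <- 0
      for (r in seq_len(repetitions)) {
        fold <- folds_list[[r]]
        for (f in seq_len(cv_folds)) {
          col <- col + 1
          tr <- fold != f
          if (length(unique(y[tr])) < 2) {
            stop_cfg("fold %d of repetition %d lost an outcome class", f, r)
          }
          fit <- balanced_rf(xm[tr, , drop = FALSE], y[tr],
                             num_trees = num_trees,
                             seed = child_seed(seed %||% 0, m * 10000 + col))
          e[m, col] <- oob_error(fit, xm[tr, , drop = FALSE], y[tr])
        }
      }
    }
    e
  })
  mean_err <- rowMeans(errs)
  sd_err <- apply(errs, 1, stats::sd)
  selected_m <- which.min(mean_err)  # which.min already ties to smaller m
  out <- data.frame(m = seq_len(M),
                    variables = vapply(seq_len(M), function(m)
                      paste(vars[seq_len(m)], collapse = ","), character(1)),
                    mean_oob_error = mean_err, sd_oob_error = sd_err,
                    stringsAsFactors = FALSE)
  structure(out, class = c("oob_curve", "data.frame"),
            selected_m = selected_m,
            selected_variables = vars[seq_len(selected_m)],
            errors = errs, cv_folds = cv_folds, repetitions = repetitions)
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin into folds
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Multivariable logistic regression with odds ratios
#'
#' Maximum-likelihood logistic fit of the binary outcome on the selected
#' predictors, categorical levels entered against their codebook reference
#' levels, life satisfaction as a rescaled numeric. Coefficients are reported
#' as odds ratios with Wald 95% confidence intervals and p-values.
#'
#' @param data data.frame with predictor columns and an `outcome` column
#'   (0/1).
#' @param variables predictors to enter (default: all codebook predictors
#'   present in `data`).
#' @param codebook predictor codebook (supplies reference levels).
#' @param alpha significance level for the confidence intervals.
#' @param on_separation what to do when (quasi-)complete separation is
#'   detected: `"error"` (default, names the offending term) or `"warn"`
#'   (keep the fit; sparse factor cells in small cohorts routinely produce
#'   quasi-separation with huge but harmless Wald intervals).
#' @return object of class `logistic_result`: data.frame with one row per
#'   non-reference level (`variable`, `level`, `coef`, `se`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`); attributes `fit` (the `glm`),
#'   `log_likelihood`, `n`.
#' @export
fit_multivariable_logistic <- function(data, variables = NULL,
                                       codebook = default_codebook(),
                                       alpha = 0.05,
                                       on_separation = c("error", "warn")) {
  on_separation <- match.arg(on_separation)
  variables <- variables %||% intersect(predictor_names(codebook), names(data))
  d <- data.frame(outcome = data$outcome)
  for (v in variables) {
    entry <- codebook[[v]]
    x <- data[[v]]
    if (!is.null(entry) && entry$type != "numeric") {
      f <- codebook_factor(x, entry, v)
      f <- stats::relevel(f, ref = entry$reference)
      d[[v]] <- f
    } else {
      d[[v]] <- as.numeric(x)
    }
  }
  cc <- stats::complete.cases(d)
  d <- d[cc, , drop = FALSE]
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(outcome ~ ., data = d, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)$coefficients
  if (sep_warn || any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)) {
    worst <- names(which.max(abs(stats::coef(fit)[-1])))
    msg <- sprintf("perfect or quasi-perfect separation detected (term '%s')",
                   worst)
    if (on_separation == "error") stop_cfg("%s", msg) else warning(msg, call. = FALSE)
  }
  zq <- stats::qnorm(1 - alpha / 2)
  rows <- rownames(sm)[-1]
  term_var <- vapply(rows, function(r) {
    hit <- variables[startsWith(r, variables)]
    hit[which.max(nchar(hit))]
  }, character(1))
  term_lev <- mapply(function(r, v) {
    lev <- sub(paste0("^", v), "", r)
    if (lev == "") "(numeric)" else lev
  }, rows, term_var)
  out <- data.frame(variable = unname(term_var), level = unname(term_lev),
                    coef = sm[-1, "Estimate"], se = sm[-1, "Std. Error"],
                    odds_ratio = exp(sm[-1, "Estimate"]),
                    ci_low = exp(sm[-1, "Estimate"] - zq * sm[-1, "Std. Error"]),
                    ci_high = exp(sm[-1, "Estimate"] + zq * sm[-1, "Std. Error"]),
                    p_value = sm[-1, "Pr(>|z|)"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("logistic_result", "data.frame"),
            fit = fit, log_likelihood = as.numeric(stats::logLik(fit)),
            n = nrow(d), variables = variables)
}

#' Variables with at least one significant level
#'
#' A categorical predictor is retained when any of its non-reference levels
#' reaches `p < alpha`; order follows the input variable order (i.e. the
#' importance ranking when the fit was built from one).
#'
#' @param result a `logistic_result`.
#' @param alpha significance threshold (default 0.05).
#' @return character vector of retained variable names.
#' @export
select_significant <- function(result, alpha = 0.05) {
  keep <- tapply(result$p_value < alpha, result$variable, any)
  vars <- attr(result, "variables")
  vars[vars %in% names(keep)[keep]]
}

#' Retrain final models on the selected variables
#'
#' Refits, from scratch on the full training partition restricted to the
#' selected predictors, both a balanced probability forest and a logistic
#' model.
#'
#' @param x encoded training feature matrix.
#' @param data training data.frame (factor predictors plus `outcome`).
#' @param variables selected predictor names (non-empty).
#' @param codebook predictor codebook.
#' @param num_trees forest size.
#' @param seed RNG seed.
#' @param on_separation passed to [fit_multivariable_logistic()].
#' @return list with `rf` (probability `ranger` fit on the selected encoded
#'   columns), `lr` (a `logistic_result`), `variables`, and `columns` (the
#'   encoded columns the forest uses).
#' @export
retrain_final <- function(x, data, variables, codebook = default_codebook(),
                          num_trees = 500, seed = NULL,
                          on_separation = "error") {
  assert_that(length(variables) > 0, "no variables selected for retraining")
  var_of <- attr(x, "variable") %||% colnames(x)
  keep <- var_of %in% variables
  xm <- x[, keep, drop = FALSE]
  y <- factor(ifelse(data$outcome == 1, "dementia", "normal"),
              levels = c("normal", "dementia"))
  rf <- balanced_rf(xm, y, num_trees = num_trees, seed = seed,
                    probability = TRUE)
  lr <- fit_multivariable_logistic(data, variables, codebook,
                                   on_separation = on_separation)
  list(rf = rf, lr = lr, variables = variables, columns = colnames(xm))
}
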