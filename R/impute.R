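#' Stratified train/test split
#'
#' Splits rows into training and testing partitions preserving the outcome
#' class proportions to within rounding.
#'
#' @param data data.frame with an `outcome` column (0/1).
#' @param test_fraction fraction assigned to the test partition.
#' @param seed RNG seed.
#' @return list with `train` and `test` data.frames (disjoint, exhaustive).
#' @export
split_train_test <- function(data, test_fraction = 0.20, seed = NULL) {
  y <- data$outcome
  assert_that(!is.null(y), "data must carry an 'outcome' column")
  tab <- table(y)
  if (length(tab) < 2 || any(tab < 2)) {
    stop_cfg("each outcome class needs at least 2 members for a stratified split")
  }
  test_idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(data)), y), function(idx) {
      k <- round(length(idx) * test_fraction)
      sample(idx, k)
    }), use.names = FALSE)
  })
  list(train = data[-test_idx, , drop = FALSE],
       test = data[sort(test_idx), , drop = FALSE])
}

#' Min-max rescaling fitted on training data
#'
#' `rescale_fit` learns the training minimum and maximum; `rescale_apply`
#' maps `x` to `(x - min) / (max - min)`. Test values outside the training
#' range map outside \[0, 1\] (a warning is emitted).
#'
#' @param x numeric vector (training column for `rescale_fit`).
#' @return `rescale_fit`: list with `min`, `max`; `rescale_apply`: rescaled
#'   vector.
#' @export
rescale_fit <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1]) || r[1] == r[2]) {
    stop_cfg("cannot min-max rescale a constant column")
  }
  list(min = r[1], max = r[2])
}

#' @rdname rescale_fit
#' @param scaler list from `rescale_fit`.
#' @export
rescale_apply <- function(x, scaler) {
  out <- (x - scaler$min) / (scaler$max - scaler$min)
  if (any(!is.na(out) & (out < 0 | out > 1))) {
    warning("rescaled values outside [0, 1]: input beyond the training range",
            call. = FALSE)
  }
  out
}

#' Encode predictors as a numeric matrix
#'
#' Codebook-driven encoding used by the distance-based imputer and the random
#' forest: ordinal and binary predictors become integer level codes, nominal
#' predictors become one-hot indicator columns, and numeric predictors pass
#' through (life satisfaction min-max rescaled when a scaler is supplied).
#' The `variable` attribute maps every encoded column back to its predictor.
#'
#' @param data data.frame holding the predictor columns.
#' @param codebook predictor codebook.
#' @param variables predictors to encode (default: all in the codebook).
#' @param scalers named list of `rescale_fit` scalers for numeric predictors.
#' @return numeric matrix with attributes `variable` (per column) and
#'   `codebook`.
#' @export
encode_features <- function(data, codebook = default_codebook(),
                            variables = predictor_names(codebook),
                            scalers = NULL) {
  cols <- list()
  var_of <- character(0)
  for (v in variables) {
    entry <- codebook[[v]]
    if (is.null(entry)) stop_cfg("variable '%s' not in codebook", v)
    x <- data[[v]]
    if (is.null(x)) stop_cfg("variable '%s' not in data", v)
    if (entry$type == "numeric") {
      x <- as.numeric(x)
      if (!is.null(scalers[[v]])) x <- rescale_apply(x, scalers[[v]])
      cols[[v]] <- x
      var_of <- c(var_of, v)
    } else if (entry$type == "nominal") {
      f <- codebook_factor(x, entry, v)
      for (lev in entry$levels) {
        nm <- paste0(v, "=", lev)
        cols[[nm]] <- ifelse(is.na(f), NA_real_, as.numeric(f == lev))
        var_of <- c(var_of, v)
      }
    } else {
      f <- codebook_factor(x, entry, v)
      cols[[v]] <- as.numeric(f)
      var_of <- c(var_of, v)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- NULL
  attr(m, "variable") <- var_of
  attr(m, "codebook") <- codebook
  m
}

#' Decode an encoded (imputed) matrix back to predictor columns
#'
#' Ordinal/binary codes are rounded to the nearest valid level code; one-hot
#' blocks take the level with the largest indicator.
#'
#' @param m matrix from [encode_features()] (typically after imputation).
#' @param codebook predictor codebook.
#' @return data.frame of predictor columns (factors and numerics).
#' @export
decode_features <- function(m, codebook = attr(m, "codebook")) {
  var_of <- attr(m, "variable")
  out <- list()
  for (v in unique(var_of)) {
    entry <- codebook[[v]]
    block <- m[, var_of == v, drop = FALSE]
    if (entry$type == "numeric") {
      out[[v]] <- as.numeric(block[, 1])
    } else if (entry$type == "nominal") {
      na_rows <- apply(block, 1, anyNA)
      filled <- block
      filled[is.na(filled)] <- -1
      idx <- max.col(filled, ties.method = "first")
      idx[na_rows & apply(block, 1, function(r) all(is.na(r)))] <- NA_integer_
      out[[v]] <- factor(entry$levels[idx], levels = entry$levels)
    } else {
      code <- pmin(pmax(round(block[, 1]), 1), length(entry$levels))
      out[[v]] <- factor(entry$levels[code], levels = entry$levels)
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# pairwise nan-Euclidean squared distances between rows of A and B:
# squared differences over mutually observed coordinates, scaled by
# p / #observed (the convention of distance-based imputers)
nan_dist2 <- function(A, B = A) {
  p <- ncol(A)
  Ma <- !is.na(A); Mb <- !is.na(B)
  A0 <- A; A0[!Ma] <- 0
  B0 <- B; B0[!Mb] <- 0
  cross <- A0 %*% t(B0)
  t1 <- (A0^2) %*% t(Mb)
  t2 <- Ma %*% t(B0^2)
  d2 <- t1 + t2 - 2 * cross
  nobs <- Ma %*% t(Mb)
  d2 <- ifelse(nobs > 0, d2 * p / nobs, Inf)
  d2[d2 < 0] <- 0  # numerical guard
  d2
}

#' K-nearest-neighbour imputation
#'
#' Fills each missing cell with the mean of that feature over the `k` nearest
#' rows, under the Euclidean distance computed on mutually observed features
#' (scaled by the fraction observed). Only rows with the feature observed are
#' candidate neighbours; when fewer than `k` such rows exist at finite
#' distance, all of them are used. Ties in distance break by row order.
#' Observed cells are never altered.
#'
#' @param x numeric matrix with `NA`s.
#' @param k number of neighbours (>= 1).
#' @param reference optional numeric matrix of donor rows (e.g. the training
#'   matrix when imputing test data); defaults to `x` itself, excluding each
#'   row as its own neighbour.
#' @return the completed matrix.
#' @export
#' @examples
#' m <- matrix(c(1, 1, 5, 1, NA, 9), ncol = 2)
#' knn_impute(m, k = 1)
knn_impute <- function(x, k, reference = NULL) {
  assert_that(k >= 1, "k must be at least 1")
  x <- as.matrix(x)
  if (!any(is.na(x))) return(x)
  self <- is.null(reference)
  ref <- if (self) x else as.matrix(reference)
  all_missing <- rowSums(!is.na(x)) == 0
  if (any(all_missing)) {
    stop_cfg("row(s) with all features missing: %s",
             paste(which(all_missing), collapse = ", "))
  }
  need <- which(rowSums(is.na(x)) > 0)
  d2 <- nan_dist2(x[need, , drop = FALSE], ref)
  out <- x
  for (ii in seq_along(need)) {
    i <- need[ii]
    for (j in which(is.na(x[i, ]))) {
      cand <- which(!is.na(ref[, j]))
      if (self) cand <- setdiff(cand, i)
      cand <- cand[is.finite(d2[ii, cand])]
      if (!length(cand)) {
        stop_cfg("no donor rows with feature %d observed", j)
      }
      ord <- cand[order(d2[ii, cand], cand)]
      nn <- ord[seq_len(min(k, length(ord)))]
      out[i, j] <- mean(ref[nn, j])
    }
  }
  out
}

#' Elbow-method selection of the number of neighbours
#'
#' Emulates missingness on a fully observed training matrix: per repetition, a
#' fraction of cells is removed completely at random, every `k` in the grid
#' imputes them, and the mean absolute error against the held-out truth is
#' recorded. The default selection rule is a one-standard-error rule: the
#' smallest `k` whose mean MAE is within one standard error of the minimum
#' mean MAE — the point where increasing `k` no longer buys a meaningful
#' improvement. `rule = "max_curvature"` instead picks the interior point of
#' maximum second difference of the mean-MAE curve (ties to the smaller `k`).
#'
#' @param x fully observed numeric matrix (rows with `NA` are dropped).
#' @param k_grid candidate neighbour counts (default 1:20).
#' @param removal_fraction fraction of cells removed per repetition
#'   (default 0.10).
#' @param repetitions number of random removals (default 30).
#' @param seed RNG seed.
#' @param rule `"one_se"` (default) or `"max_curvature"`.
#' @return object of class `imputation_report`: list with `k_grid`,
#'   `mae_mean`, `mae_sd`, `chosen_k`, `repetitions`, `removal_fraction`,
#'   `rule`, and the per-repetition `mae` matrix (repetitions x k).
#' @export
elbow_select_k <- function(x, k_grid = 1:20, removal_fraction = 0.10,
                           repetitions = 30, seed = NULL,
                           rule = c("one_se", "max_curvature")) {
  rule <- match.arg(rule)
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); p <- ncol(x)
  kmax <- max(k_grid)
  if (n - ceiling(n * removal_fraction) < kmax + 1) {
    stop_cfg("complete submatrix too small (%d rows) for removal fraction %.2f and k up to %d",
             n, removal_fraction, kmax)
  }
  ncell <- n * p
  nrm <- max(1, round(removal_fraction * ncell))
  mae <- with_seed(seed, {
    vapply(seq_len(repetitions), function(r) {
      cells <- sample.int(ncell, nrm)
      xm <- x
      xm[cells] <- NA
      # guard: a fully blanked row cannot be imputed; restore one cell
      blank <- which(rowSums(!is.na(xm)) == 0)
      for (i in blank) {
        j <- sample.int(p, 1)
        xm[i, j] <- x[i, j]
      }
      removed <- which(is.na(xm))
      mae_for_all_k(xm, x, removed, k_grid)
    }, numeric(length(k_grid)))
  })
  mae <- t(mae)  # repetitions x k
  mae_mean <- colMeans(mae)
  mae_sd <- apply(mae, 2, stats::sd)
  chosen_k <- choose_elbow_k(k_grid, mae_mean, mae_sd, repetitions, rule)
  structure(list(k_grid = k_grid, mae_mean = mae_mean, mae_sd = mae_sd,
                 chosen_k = chosen_k, repetitions = repetitions,
                 removal_fraction = removal_fraction, rule = rule, mae = mae),
            class = "imputation_report")
}

choose_elbow_k <- function(k_grid, mae_mean, mae_sd, repetitions, rule) {
  if (rule == "max_curvature") {
    if (length(k_grid) < 3) return(k_grid[which.min(mae_mean)])
    d2 <- diff(mae_mean, differences = 2)  # index i -> k_grid[i + 1]
    return(k_grid[which.max(d2) + 1])
  }
  i_min <- which.min(mae_mean)
  se <- mae_sd[i_min] / sqrt(repetitions)
  k_grid[min(which(mae_mean <= mae_mean[i_min] + se))]
}

# MAE over removed cells for every k at once: neighbour distances are
# computed once per repetition and the k nearest means read off cumulatively
mae_for_all_k <- function(xm, truth, removed, k_grid) {
  n <- nrow(xm); p <- ncol(xm)
  need <- unique(((removed - 1) %% n) + 1)
  d2 <- nan_dist2(xm[need, , drop = FALSE], xm)
  kmax <- max(k_grid)
  err_sum <- matrix(0, length(k_grid), 1)
  for (ii in seq_along(need)) {
    i <- need[ii]
    for (j in which(is.na(xm[i, ]))) {
      cand <- which(!is.na(xm[, j]))
      cand <- setdiff(cand, i)
      ord <- cand[order(d2[ii, cand], cand)]
      vals <- xm[ord, j][seq_len(min(kmax, length(ord)))]
      cm <- cumsum(vals) / seq_along(vals)
      est <- cm[pmin(k_grid, length(vals))]
      err_sum <- err_sum + abs(est - truth[i, j])
    }
  }
  as.numeric(err_sum / length(removed))
}

#' Fit-on-train preprocessing of both partitions
#'
#' Rescales the numeric predictors (life satisfaction) with training min/max,
#' selects `k` by the elbow method on the complete training submatrix, and
#' imputes both partitions with the training-fitted imputer (training rows are
#' the donors for test-set imputation). No statistic is ever computed from
#' test rows.
#'
#' @param train,test data.frames carrying the predictor columns.
#' @param codebook predictor codebook.
#' @param k_grid,removal_fraction,repetitions,seed,rule passed to
#'   [elbow_select_k()].
#' @param k fixed number of neighbours; when `NULL` (default) the elbow choice
#'   is used.
#' @return list with `train` and `test` (completed predictor data.frames),
#'   `report` (the [elbow_select_k()] report, or `NULL` when `k` was fixed),
#'   `k`, `scalers`, and the encoded matrices `train_matrix`, `test_matrix`.
#' @export
preprocess_pipeline <- function(train, test, codebook = default_codebook(),
                                k_grid = 1:20, removal_fraction = 0.10,
                                repetitions = 30, seed = NULL, k = NULL,
                                rule = "one_se") {
  scalers <- list()
  for (v in predictor_names(codebook)) {
    if (codebook[[v]]$type == "numeric" && isTRUE(codebook[[v]]$rescale)) {
      scalers[[v]] <- rescale_fit(as.numeric(train[[v]]))
    }
  }
  Xtr <- encode_features(train, codebook, scalers = scalers)
  Xte <- encode_features(test, codebook, scalers = scalers)
  report <- NULL
  if (is.null(k)) {
    report <- elbow_select_k(Xtr, k_grid = k_grid,
                             removal_fraction = removal_fraction,
                             repetitions = repetitions, seed = seed,
                             rule = rule)
    k <- report$chosen_k
  }
  tr_done <- knn_impute(Xtr, k)
  te_done <- if (any(is.na(Xte))) knn_impute(Xte, k, reference = tr_done) else Xte
  keep_attr <- function(m, template) {
    attr(m, "variable") <- attr(template, "variable")
    attr(m, "codebook") <- attr(template, "codebook")
    m
  }
  tr_done <- keep_attr(tr_done, Xtr)
  te_done <- keep_attr(te_done, Xte)
  list(train = decode_features(tr_done), test = decode_features(te_done),
       report = report, k = k, scalers = scalers,
       train_matrix = tr_done, test_matrix = te_done)
}
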