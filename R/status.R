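#' Select the normative subsample
#'
#' The regression norms are fitted on "healthy" battery completers. A record
#' is excluded when any of the following holds: self-reported visual
#' impairment; poor (recoded) hearing; a depression diagnosis or a CES-D8
#' depressive-symptom flag (score >= 4); history of stroke, Alzheimer's or
#' Parkinson's disease; excessive alcohol intake under the NIAAA sex-specific
#' rule; memory complaints (self- or informant-reported); difficulty in the
#' four cognition-related IADLs; or missing battery results. Records with
#' missing values on any criterion are excluded.
#'
#' @param scored a scored cohort from [score_cohort()].
#' @return list with `ids` (row indices of the normative subsample) and
#'   `report` (named exclusion counts; a record can match several criteria).
#' @export
select_normative_subsample <- function(scored) {
  crit <- list(
    visual_impairment = scored$visual_impairment == "yes",
    poor_hearing = scored$hearing3 == "poor",
    depression = scored$depression_diagnosis == "yes" |
      scored$depressive_symptoms == "yes",
    neuro_history = scored$stroke == "yes" | scored$alzheimer == "yes" |
      scored$parkinson == "yes",
    excessive_alcohol_niaaa = scored$excessive_niaaa,
    memory_complaint = scored$memory_complaint == "yes",
    iadl_impairment = scored$iadl_count >= 4,
    missing_battery = is.na(scored$global_z)
  )
  crit <- lapply(crit, function(x) is.na(x) | x)  # missing criterion data -> excluded
  excluded <- Reduce(`|`, crit)
  ids <- which(!excluded)
  if (!length(ids)) {
    stop_cfg("normative subsample is empty: norms cannot be fitted")
  }
  list(ids = ids, report = vapply(crit, sum, integer(1)),
       n_norm = length(ids))
}

#' Fit regression-based norms for the global cognitive score
#'
#' Ordinary least squares of the standardised global cognitive score on age
#' (years), sex (0 = male, 1 = female) and education (years of schooling),
#' fitted on the normative subsample. Individual deviations are later
#' standardised by the root mean square error of these normative residuals.
#'
#' @param scored scored cohort.
#' @param ids normative subsample indices from [select_normative_subsample()].
#' @return object of class `norm_model`: list with `intercept`, `coef_age`,
#'   `coef_sex`, `coef_education_years`, `rmse_residual`, `r_squared`,
#'   `f_statistic`, `p_values`, `n_norm`.
#' @export
fit_norm_model <- function(scored, ids) {
  d <- data.frame(global_z = scored$global_z[ids],
                  age_years = scored$age_years[ids],
                  sex01 = scored$sex01[ids],
                  education_years = scored$education_years[ids])
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) <= 10) stop_cfg("normative subsample too small (n = %d)", nrow(d))
  X <- cbind(1, d$age_years, d$sex01, d$education_years)
  if (qr(X)$rank < ncol(X)) stop_cfg("singular normative design matrix")
  fit <- stats::lm(global_z ~ age_years + sex01 + education_years, data = d)
  res <- stats::residuals(fit)
  rmse <- sqrt(mean(res^2))
  if (rmse < 1e-10 * max(1, stats::sd(d$global_z))) {
    stop_cfg("normative fit is exact (zero residual RMSE); norms undefined")
  }
  s <- summary(fit)
  structure(list(
    intercept = unname(stats::coef(fit)[1]),
    coef_age = unname(stats::coef(fit)["age_years"]),
    coef_sex = unname(stats::coef(fit)["sex01"]),
    coef_education_years = unname(stats::coef(fit)["education_years"]),
    rmse_residual = rmse,
    r_squared = s$r.squared,
    f_statistic = unname(s$fstatistic["value"]),
    p_values = s$coefficients[, "Pr(>|t|)"],
    n_norm = nrow(d)
  ), class = "norm_model")
}

#' @export
print.norm_model <- function(x, ...) {
  cat(sprintf(
    "Regression-based norms (n = %d)\n  global_z = %.4f %+.4f*age %+.4f*sex(F) %+.4f*education\n  residual RMSE = %.4f, R^2 = %.3f, F = %.2f\n",
    x$n_norm, x$intercept, x$coef_age, x$coef_sex, x$coef_education_years,
    x$rmse_residual, x$r_squared, x$f_statistic))
  invisible(x)
}

#' Serialize / load a norm model as JSON
#' @param norm a `norm_model`.
#' @param path file path.
#' @return `write_norm_model` returns `path` invisibly; `read_norm_model` the
#'   model.
#' @export
write_norm_model <- function(norm, path) {
  jsonlite::write_json(unclass(norm), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_norm_model
#' @export
read_norm_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "norm_model")
}

#' Residual z-score against the norms
#'
#' Standardised deviation of the observed global cognitive score from the
#' norm-predicted score: `(observed - predicted) / rmse_residual`. Missing
#' covariates or score give a missing result.
#'
#' @param global_z observed global cognitive score(s).
#' @param age_years,sex01,education_years covariates (sex coded 0 male /
#'   1 female).
#' @param norm a `norm_model`.
#' @return numeric vector of residual z-scores.
#' @export
residual_z <- function(global_z, age_years, sex01, education_years, norm) {
  pred <- norm$intercept + norm$coef_age * age_years + norm$coef_sex * sex01 +
    norm$coef_education_years * education_years
  (global_z - pred) / norm$rmse_residual
}

#' Classify cognitive status
#'
#' Battery pathway: cognitive impairment is a residual z-score at or below
#' -1.5; functional impairment is difficulty in at least `iadl_threshold` of
#' the four cognition-related IADLs. Both together define dementia; cognitive
#' without functional impairment defines cognitive impairment. Functional
#' impairment without a cognitive deficit is attributed to non-cognitive
#' causes (normal) when the informant IQCODE is below 3.22 or unavailable,
#' and to cognitive decline (impairment) when the IQCODE is 3.22 or above.
#' Proxy pathway (battery not completed): the IQCODE category is the status.
#'
#' @param z_resid residual z-score (battery pathway; `NA` for proxies).
#' @param iadl_count number of cognition-related IADL difficulties (0-4).
#' @param iqcode_score informant IQCODE score (`NA` when unavailable).
#' @param proxy_flag logical: informant pathway.
#' @param z_cut cognitive-impairment cut (default -1.5).
#' @param iadl_threshold functional-impairment threshold (default 4).
#' @return factor vector with levels normal/impairment/dementia; `NA` when
#'   neither pathway's inputs are available. The `source` attribute records
#'   the pathway per record (`"battery"`/`"proxy"`).
#' @export
classify_status <- function(z_resid, iadl_count, iqcode_score, proxy_flag,
                            z_cut = -1.5, iadl_threshold = 4) {
  n <- max(length(z_resid), length(iadl_count), length(iqcode_score),
           length(proxy_flag))
  z_resid <- rep_len(z_resid, n)
  iadl_count <- rep_len(iadl_count, n)
  iqcode_score <- rep_len(iqcode_score, n)
  proxy_flag <- rep_len(proxy_flag, n)
  out <- rep(NA_character_, n)
  src <- rep(NA_character_, n)

  pr <- which(proxy_flag)
  out[pr] <- as.character(iqcode_category(iqcode_score[pr]))
  src[pr] <- "proxy"

  bt <- which(!proxy_flag & !is.na(z_resid))
  cog <- z_resid[bt] <= z_cut
  fun <- !is.na(iadl_count[bt]) & iadl_count[bt] >= iadl_threshold
  lab <- ifelse(cog & fun, "dementia",
                ifelse(cog, "impairment",
                       ifelse(fun & !is.na(iqcode_score[bt]) &
                                iqcode_score[bt] >= 3.22,
                              "impairment", "normal")))
  out[bt] <- lab
  src[bt] <- "battery"
  structure(factor(out, levels = c("normal", "impairment", "dementia")),
            source = src)
}

#' Derive cognitive status for a scored cohort
#'
#' Runs the full derivation: normative subsample selection, norm fitting,
#' residual z-scores, and the status rules, appending `z_resid` and `status`
#' columns.
#'
#' @param scored scored cohort from [score_cohort()].
#' @param z_cut,iadl_threshold passed to [classify_status()].
#' @return list with `cohort` (labelled), `norm_model`, `normative` (the
#'   subsample selection).
#' @export
derive_status <- function(scored, z_cut = -1.5, iadl_threshold = 4) {
  normative <- select_normative_subsample(scored)
  norm <- fit_norm_model(scored, normative$ids)
  scored$z_resid <- residual_z(scored$global_z, scored$age_years,
                               scored$sex01, scored$education_years, norm)
  scored$status <- classify_status(scored$z_resid, scored$iadl_count,
                                   scored$iqcode_score, scored$proxy_flag,
                                   z_cut = z_cut,
                                   iadl_threshold = iadl_threshold)
  list(cohort = scored, norm_model = norm, normative = normative)
}

#' Build the binary analytic dataset
#'
#' Retains records with normal cognition or dementia, dropping the
#' intermediate cognitive-impairment group and records without a status; the
#' binary outcome codes dementia as 1.
#'
#' @param labeled cohort with a `status` column.
#' @return list with `data` (retained records plus `outcome` 0/1) and
#'   `report` (counts: input, retained, excluded impairment, excluded missing
#'   status).
#' @export
build_binary_dataset <- function(labeled) {
  status <- labeled$status
  keep <- !is.na(status) & status %in% c("normal", "dementia")
  report <- c(n_input = nrow(labeled),
              n_retained = sum(keep),
              n_excluded_impairment = sum(!is.na(status) & status == "impairment"),
              n_missing_status = sum(is.na(status)))
  data <- labeled[keep, , drop = FALSE]
  if (length(unique(data$status[!is.na(data$status)])) < 2) {
    stop_cfg("binary dataset needs both classes; got %s",
             paste(unique(as.character(data$status)), collapse = ", "))
  }
  data$outcome <- as.integer(data$status == "dementia")
  list(data = data, report = report)
}
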