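test_that("classify_status matches the independently coded rule table on a grid", {
  grid <- expand.grid(z = c(-2, -1.5, -1.4, -1, 0),
                      iadl = 0:4,
                      iqcode = c(NA, 3.0, 3.21, 3.22, 3.3, 3.47, 3.48, 4.2),
                      proxy = c(FALSE, TRUE))
  got <- classify_status(ifelse(grid$proxy, NA, grid$z), grid$iadl,
                         grid$iqcode, grid$proxy)
  want <- mapply(function(z, iadl, iq, px) {
    oracle_classify(if (px) NA else z, iadl, iq, px)
  }, grid$z, grid$iadl, grid$iqcode, grid$proxy)
  expect_equal(as.character(got), unname(want))
  # pathway bookkeeping
  src <- attr(got, "source")
  expect_true(all(src[grid$proxy] == "proxy"))
  expect_true(all(src[!grid$proxy] == "battery"))
})

test_that("boundary cases of the dementia rule behave as specified", {
  expect_equal(as.character(classify_status(-1.6, 4, NA, FALSE)), "dementia")
  expect_equal(as.character(classify_status(-1.6, 2, NA, FALSE)), "impairment")
  expect_equal(as.character(classify_status(-1.5, 4, NA, FALSE)), "dementia")
  expect_equal(as.character(classify_status(0, 4, 3.0, FALSE)), "normal")
  expect_equal(as.character(classify_status(0, 4, 3.3, FALSE)), "impairment")
  expect_true(is.na(classify_status(NA, 2, NA, FALSE)))
})

test_that("normative subsample excludes each stated condition", {
  co <- generate_cohort(cohort_config(n_participants = 600, seed = 23))
  sc <- score_cohort(co)
  sel <- select_normative_subsample(sc)
  ids <- sel$ids
  expect_true(all(sc$cesd_score[ids] < 4))
  expect_true(all(sc$visual_impairment[ids] == "no"))
  expect_true(all(sc$hearing3[ids] != "poor"))
  expect_true(all(sc$stroke[ids] == "no" & sc$alzheimer[ids] == "no" &
                    sc$parkinson[ids] == "no"))
  expect_true(all(!sc$excessive_niaaa[ids]))
  expect_true(all(sc$memory_complaint[ids] == "no"))
  expect_true(all(sc$iadl_count[ids] < 4))
  expect_true(all(!is.na(sc$global_z[ids])))
  # a record flagged on CES-D8 alone is excluded
  sc2 <- sc
  sc2$cesd_score[ids[1]] <- 4
  sc2$depressive_symptoms[ids[1]] <- "yes"
  expect_false(ids[1] %in% select_normative_subsample(sc2)$ids)
  # degenerate cohort where everyone fails
  sc3 <- sc
  sc3$memory_complaint[] <- "yes"
  expect_error(select_normative_subsample(sc3), "empty")
})

test_that("norm fitting agrees with closed-form OLS and recovers planted coefficients", {
  d <- make_linear_norm_data(n = 3000, sigma = 0.8, seed = 5)
  norm <- fit_norm_model(d, seq_len(nrow(d)))
  X <- cbind(1, d$age_years, d$sex01, d$education_years)
  beta <- solve(t(X) %*% X, t(X) %*% d$global_z)
  expect_equal(norm$intercept, beta[1], tolerance = 1e-8)
  expect_equal(norm$coef_age, beta[2], tolerance = 1e-8)
  expect_equal(norm$coef_sex, beta[3], tolerance = 1e-8)
  expect_equal(norm$coef_education_years, beta[4], tolerance = 1e-8)
  res <- d$global_z - X %*% beta
  expect_equal(norm$rmse_residual, sqrt(mean(res^2)), tolerance = 1e-10)
  # planted values recovered within 3 standard errors
  se <- summary(stats::lm(global_z ~ age_years + sex01 + education_years,
                          d))$coefficients[, 2]
  expect_lt(abs(norm$coef_age - (-0.03)), 3 * se[2])
  expect_lt(abs(norm$coef_education_years - 0.04), 3 * se[4])
  expect_gt(norm$coef_education_years, 0)
  # rmse approaches the planted noise SD
  expect_lt(abs(norm$rmse_residual - 0.8), 0.05)
  # exact-fit limit routes to the flagged error path
  d0 <- make_linear_norm_data(n = 200, sigma = 0, seed = 6)
  expect_error(fit_norm_model(d0, seq_len(nrow(d0))), "exact")
})

test_that("residual z-scores satisfy their defining identities", {
  d <- make_linear_norm_data(n = 2000, sigma = 0.7, seed = 9)
  norm <- fit_norm_model(d, seq_len(nrow(d)))
  pred <- norm$intercept + norm$coef_age * 60 + norm$coef_sex * 1 +
    norm$coef_education_years * 8
  expect_equal(residual_z(pred, 60, 1, 8, norm), 0, tolerance = 1e-12)
  expect_equal(residual_z(pred - norm$rmse_residual, 60, 1, 8, norm), -1,
               tolerance = 1e-12)
  z <- residual_z(d$global_z, d$age_years, d$sex01, d$education_years, norm)
  expect_lt(abs(mean(z)), 1e-10)
  expect_equal(stats::sd(z), 1, tolerance = 1e-3)
  expect_true(is.na(residual_z(0.5, NA, 1, 8, norm)))
})

test_that("under Gaussian residuals the -1.5 cut captures about phi(-1.5)", {
  d <- make_linear_norm_data(n = 20000, sigma = 1, seed = 12)
  norm <- fit_norm_model(d, seq_len(nrow(d)))
  z <- residual_z(d$global_z, d$age_years, d$sex01, d$education_years, norm)
  expect_lt(abs(mean(z <= -1.5) - stats::pnorm(-1.5)), 0.01)
})

test_that("binary dataset construction conserves counts and reports exclusions", {
  co <- generate_cohort(cohort_config(n_participants = 1200, seed = 17))
  dv <- derive_status(score_cohort(co))
  bin <- build_binary_dataset(dv$cohort)
  rep <- bin$report
  expect_equal(unname(rep["n_retained"] + rep["n_excluded_impairment"] +
                        rep["n_missing_status"]), 1200)
  expect_true(all(bin$data$status %in% c("normal", "dementia")))
  expect_equal(bin$data$outcome, as.integer(bin$data$status == "dementia"))
  # conservation of the three-way split
  expect_equal(sum(table(dv$cohort$status)) +
                 sum(is.na(dv$cohort$status)), 1200)
  # no impairment cases -> everything retained
  sub <- dv$cohort[dv$cohort$status != "impairment", ]
  expect_equal(build_binary_dataset(sub)$report[["n_retained"]], nrow(sub))
  # fewer than two classes -> error
  one <- dv$cohort[dv$cohort$status == "normal", ]
  expect_error(build_binary_dataset(one), "both classes")
})

test_that("norm model JSON round trip is lossless", {
  d <- make_linear_norm_data(n = 500, sigma = 0.5, seed = 3)
  norm <- fit_norm_model(d, seq_len(nrow(d)))
  f <- tempfile(fileext = ".json")
  write_norm_model(norm, f)
  back <- read_norm_model(f)
  expect_equal(back$intercept, norm$intercept)
  expect_equal(back$rmse_residual, norm$rmse_residual)
})
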