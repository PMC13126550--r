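#' Cohort generator configuration
#'
#' Defines the study conditions the synthetic cohort emulates: cohort size and
#' dementia prevalence matching the published group sizes (845 of 8,807),
#' class-conditional predictor profiles transcribed from the published model
#' table, an intermediate cognitive-impairment fraction matching the 528 of
#' 9,412 participants the study excluded from its binary analysis, the
#' fraction of participants routed to informant (IQCODE) assessment, and
#' per-variable missingness rates inside the printed 0.1-10.8% range.
#'
#' @param n_participants cohort size (default 8,807, the published group total).
#' @param dementia_prevalence marginal dementia fraction in \[0, 1).
#' @param impairment_fraction marginal cognitive-impairment fraction (the group
#'   excluded before binary modelling); default 528/9412.
#' @param proxy_fraction fraction assessed via informant IQCODE instead of the
#'   battery.
#' @param predictor_profiles class-conditional category probabilities, as from
#'   [default_predictor_profiles()].
#' @param missingness_rates named per-variable-group missingness fractions in
#'   \[0, 1); see [default_missingness_rates()].
#' @param latent_effects optional named list of per-predictor log-odds
#'   contributions; when supplied, predictors are sampled from pooled marginals
#'   and status follows a logistic link with these coefficients (used for
#'   parameter-recovery simulation) instead of class-conditional profiles.
#' @param battery_noise_sd Gaussian noise SD added to planted battery raw
#'   scores before rounding (0 keeps the status rules exactly recoverable).
#' @param label_noise fraction of records whose cognition items are planted
#'   under a wrong status (stress testing; default 0).
#' @param seed default generation seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 8807,
                          dementia_prevalence = 0.096,
                          impairment_fraction = 528 / 9412,
                          proxy_fraction = 0.05,
                          predictor_profiles = default_predictor_profiles(),
                          missingness_rates = default_missingness_rates(),
                          latent_effects = NULL,
                          battery_noise_sd = 0,
                          label_noise = 0,
                          seed = 1L) {
  assert_that(length(n_participants) == 1 && n_participants >= 1,
              "n_participants must be a positive integer")
  assert_that(dementia_prevalence >= 0 && dementia_prevalence < 1,
              "dementia_prevalence must be in [0, 1)")
  assert_that(impairment_fraction >= 0 && impairment_fraction < 1 &&
                dementia_prevalence + impairment_fraction < 1,
              "impairment_fraction must leave room for the other classes")
  assert_that(proxy_fraction >= 0 && proxy_fraction <= 1,
              "proxy_fraction must be in [0, 1]")
  if (length(missingness_rates)) {
    assert_that(all(missingness_rates >= 0) && all(missingness_rates < 1),
                "missingness rates must be in [0, 1)")
  }
  for (v in unique(predictor_profiles$variable)) {
    p <- predictor_profiles[predictor_profiles$variable == v, ]
    for (col in c("p_normal", "p_dementia")) {
      if (abs(sum(p[[col]]) - 1) > 1e-9) {
        stop_cfg("profile probabilities for predictor '%s' (%s) sum to %.12f, not 1",
                 v, col, sum(p[[col]]))
      }
      if (any(p[[col]] < 0)) {
        stop_cfg("profile probabilities for predictor '%s' must be non-negative", v)
      }
    }
  }
  structure(list(
    n_participants = as.integer(n_participants),
    dementia_prevalence = dementia_prevalence,
    impairment_fraction = impairment_fraction,
    proxy_fraction = proxy_fraction,
    predictor_profiles = predictor_profiles,
    missingness_rates = missingness_rates,
    latent_effects = latent_effects,
    battery_noise_sd = battery_noise_sd,
    label_noise = label_noise,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Default per-variable missingness rates
#'
#' Thirteen variable groups carry missing values at rates inside the printed
#' 0.1-10.8% range; sex, age, education, social isolation and occupational
#' status are complete, as are the cognition instruments that define status
#' (battery, IADL, IQCODE), so item missingness never alters derived status.
#'
#' @return named numeric vector of rates.
#' @export
default_missingness_rates <- function() {
  c(life_satisfaction = 0.108, ipaq = 0.063, hgs = 0.052, cesd = 0.034,
    bmi = 0.021, loneliness = 0.012, high_cholesterol = 0.011,
    retinopathy = 0.009, diabetes = 0.008, hearing = 0.006, smoking = 0.004,
    alcohol = 0.003, marital_status = 0.001)
}

# variable groups -> raw cohort columns, for missingness injection
missingness_groups <- function() {
  list(
    life_satisfaction = "life_satisfaction",
    bmi = "weight_kg",
    hgs = c("hgs_trial1", "hgs_trial2", "hgs_trial3"),
    ipaq = c("ipaq_walk_days", "ipaq_walk_min", "ipaq_mod_days",
             "ipaq_mod_min", "ipaq_vig_days", "ipaq_vig_min"),
    cesd = sprintf("cesd_%d", 1:8),
    loneliness = "loneliness",
    hearing = "hearing_rating",
    high_cholesterol = "high_cholesterol",
    diabetes = "diabetes",
    smoking = "smoking",
    alcohol = c("alcohol_days_week", "alcohol_drinks_day"),
    retinopathy = "retinopathy",
    marital_status = "marital_status"
  )
}

# sample a level per record given class-conditional profiles
sample_profile <- function(n, status, profile) {
  out <- character(n)
  p_for <- list(normal = profile$p_normal, impairment = profile$p_normal,
                dementia = profile$p_dementia)
  for (cl in unique(as.character(status))) {
    idx <- which(status == cl)
    if (length(idx)) {
      out[idx] <- sample(profile$level, length(idx), replace = TRUE,
                         prob = p_for[[cl]])
    }
  }
  out
}

# pooled marginal sampling (latent-effects mode)
sample_pooled <- function(n, profile, prevalence) {
  p <- (1 - prevalence) * profile$p_normal + prevalence * profile$p_dementia
  sample(profile$level, n, replace = TRUE, prob = p / sum(p))
}

#' Generate a synthetic cohort
#'
#' Draws per-participant records with a planted cognitive status. In the
#' default (profile) mode, status is sampled first and every predictor is
#' drawn from its class-conditional profile; raw instrument fields (weight and
#' height, handgrip trials, IPAQ days/minutes, CES-D8 items, contact items,
#' hearing rating) are then constructed so that the package's scorers recover
#' the sampled category. Battery items, IADL difficulties and informant IQCODE
#' items are planted by [plant_latent_cognition()] so that the full
#' scoring -> regression-norms -> status-rule pipeline reproduces the planted
#' status exactly when noise is zero. Finally, per-variable missingness is
#' injected at the configured rates.
#'
#' With `latent_effects` set in the config, predictors are drawn from pooled
#' marginals and status follows a logistic link with the supplied log-odds
#' contributions (the intercept is calibrated to the configured prevalence);
#' this mode supports parameter-recovery simulations.
#'
#' @param config a [cohort_config()].
#' @param seed overrides `config$seed`.
#' @param items generate instrument items and plant cognition (default TRUE).
#'   `items = FALSE` returns the predictor-level table only (columns are the
#'   18 candidate predictors plus `id` and `true_status`), for simulation
#'   studies that skip the status-derivation stage.
#' @return a data.frame of participant records; `true_status` is the
#'   generator's planted label and is never used by the pipeline stages.
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL,
                            items = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- seed %||% config$seed
  with_seed(seed, generate_cohort_impl(config, items))
}

generate_cohort_impl <- function(config, items) {
  n <- config$n_participants
  prof <- config$predictor_profiles
  pr <- function(v) prof[prof$variable == v, ]
  cb <- default_codebook()
  statuses <- c("normal", "impairment", "dementia")

  if (is.null(config$latent_effects)) {
    probs <- c(1 - config$dementia_prevalence - config$impairment_fraction,
               config$impairment_fraction, config$dementia_prevalence)
    true_status <- sample(statuses, n, replace = TRUE, prob = probs)
    draw <- function(v) sample_profile(n, true_status, pr(v))
  } else {
    draw <- function(v) sample_pooled(n, pr(v), config$dementia_prevalence)
  }

  cat_vars <- c("education_level", "age_group", "sex", "occupation_30d",
                "marital_status", "skin_color", "bmi_band", "hgs_band",
                "activity", "loneliness", "hearing3", "depressive_symptoms",
                "high_cholesterol", "diabetes", "smoking", "social_isolation",
                "retinopathy", "visual_impairment", "depression_diagnosis",
                "stroke", "alzheimer", "parkinson", "memory_complaint")
  lv <- lapply(cat_vars, function(v) draw(v))
  names(lv) <- cat_vars
  life_satisfaction <- as.integer(draw("life_satisfaction"))

  if (!is.null(config$latent_effects)) {
    eta <- latent_eta(lv, life_satisfaction, config$latent_effects, cb)
    delta <- tryCatch(
      stats::uniroot(function(c) mean(stats::plogis(eta + c)) -
                       config$dementia_prevalence,
                     interval = c(-30, 30))$root,
      error = function(e) stop_cfg("cannot calibrate latent intercept to prevalence %.3f",
                                   config$dementia_prevalence))
    true_status <- ifelse(stats::runif(n) < stats::plogis(eta + delta),
                          "dementia", "normal")
    if (config$impairment_fraction > 0) {
      imp <- stats::runif(n) < config$impairment_fraction
      true_status[imp] <- "impairment"
    }
  }

  out <- data.frame(id = seq_len(n))
  out$true_status <- factor(true_status, levels = statuses)
  for (v in c("age_group", "sex", "education_level", "occupation_30d",
              "marital_status", "skin_color")) {
    out[[v]] <- codebook_factor(lv[[v]], cb[[v]], v)
  }
  out$life_satisfaction <- life_satisfaction

  if (!items) {
    for (v in c("bmi_band", "hgs_band", "activity", "loneliness", "hearing3",
                "depressive_symptoms", "high_cholesterol", "diabetes",
                "smoking", "social_isolation", "retinopathy")) {
      out[[v]] <- codebook_factor(lv[[v]], cb[[v]], v)
    }
    return(out)
  }

  out$proxy_flag <- stats::runif(n) < config$proxy_fraction

  # anthropometry consistent with the sampled BMI band
  bmi_lo <- c(severely_underweight = 13.5, underweight = 16,
              normal_weight = 18.5, overweight = 25, obese_1 = 30,
              obese_2 = 35, obese_3 = 40)
  bmi_hi <- c(severely_underweight = 16, underweight = 18.5,
              normal_weight = 25, overweight = 30, obese_1 = 35,
              obese_2 = 40, obese_3 = 45)
  bmi <- stats::runif(n, bmi_lo[lv$bmi_band], bmi_hi[lv$bmi_band])
  height <- ifelse(lv$sex == "male",
                   stats::rnorm(n, 1.70, 0.06), stats::rnorm(n, 1.58, 0.055))
  height <- pmin(pmax(height, 1.40), 1.95)
  out$height_m <- round(height, 3)
  out$weight_kg <- round(bmi * out$height_m^2, 2)

  # handgrip trials consistent with the sampled band
  norms <- hgs_norms_synthetic()
  nkey <- paste(norms$sex, norms$age_group)
  idx <- match(paste(lv$sex, lv$age_group), nkey)
  cuts <- as.matrix(norms[idx, c("p20", "p40", "p60", "p80")])
  band_i <- match(lv$hgs_band, cb$hgs_band$levels)
  lo <- cbind(pmax(cuts[, 1] - 8, 1), cuts[, 1], cuts[, 2], cuts[, 3],
              cuts[, 4])[cbind(seq_len(n), band_i)]
  hi <- cbind(cuts[, 1], cuts[, 2], cuts[, 3], cuts[, 4],
              cuts[, 4] + 8)[cbind(seq_len(n), band_i)]
  hgs_value <- lo + stats::runif(n) * (hi - lo) * 0.999
  inability <- lv$hgs_band == "low" & stats::runif(n) < 0.06
  hgs_value[inability] <- 0
  out$hgs_trial1 <- out$hgs_trial2 <- out$hgs_trial3 <- round(hgs_value, 2)
  out$hgs_trial1[inability] <- out$hgs_trial2[inability] <-
    out$hgs_trial3[inability] <- NA_real_
  out$hgs_inability <- inability

  # IPAQ fields consistent with the sampled activity level
  act <- lv$activity
  z6 <- function() numeric(n)
  wd <- z6(); wm <- z6(); md <- z6(); mm <- z6(); vd <- z6(); vm <- z6()
  i_low <- act == "low"
  lowsome <- i_low & stats::runif(n) < 0.5
  wd[lowsome] <- sample(1:2, sum(lowsome), replace = TRUE)
  wm[lowsome] <- sample(c(10, 15, 20), sum(lowsome), replace = TRUE)
  i_mod <- act == "moderate"
  mod_walk <- i_mod & stats::runif(n) < 0.5
  wd[mod_walk] <- 5
  wm[mod_walk] <- 30 + sample(0:25, sum(mod_walk), replace = TRUE)
  mod_mod <- i_mod & !mod_walk
  md[mod_mod] <- 5
  mm[mod_mod] <- 30 + sample(0:20, sum(mod_mod), replace = TRUE)
  i_high <- act == "high"
  vd[i_high] <- 4
  vm[i_high] <- 40 + sample(0:20, sum(i_high), replace = TRUE)
  wd[i_high] <- 5
  wm[i_high] <- 30
  out$ipaq_walk_days <- wd; out$ipaq_walk_min <- wm
  out$ipaq_mod_days <- md; out$ipaq_mod_min <- mm
  out$ipaq_vig_days <- vd; out$ipaq_vig_min <- vm

  # CES-D8 items consistent with the sampled depressive-symptom flag
  dep <- lv$depressive_symptoms == "yes"
  score <- integer(n)
  score[dep] <- sample(4:8, sum(dep), replace = TRUE,
                       prob = c(0.42, 0.26, 0.16, 0.10, 0.06))
  score[!dep] <- sample(0:3, sum(!dep), replace = TRUE,
                        prob = c(0.30, 0.30, 0.22, 0.18))
  cesd <- plant_cesd_items(score)
  for (j in 1:8) out[[sprintf("cesd_%d", j)]] <- cesd[, j]

  # contact items consistent with the sampled social-isolation flag
  lvc <- contact_levels()
  iso <- lv$social_isolation == "yes"
  contact <- matrix(NA_character_, n, 3)
  contact[iso, ] <- lvc[3 + sample.int(3, 3 * sum(iso), replace = TRUE)]
  nn <- sum(!iso)
  contact[!iso, 1] <- lvc[sample.int(3, nn, replace = TRUE)]
  contact[!iso, 2] <- lvc[sample.int(6, nn, replace = TRUE)]
  contact[!iso, 3] <- lvc[sample.int(6, nn, replace = TRUE)]
  out$contact_children <- contact[, 1]
  out$contact_relatives <- contact[, 2]
  out$contact_friends <- contact[, 3]

  # five-level hearing rating consistent with the recoded level
  hr <- character(n)
  g <- lv$hearing3 == "good"
  hr[g] <- sample(c("very good or excellent", "good"), sum(g),
                  replace = TRUE, prob = c(0.35, 0.65))
  hr[lv$hearing3 == "fair"] <- "fair"
  p <- lv$hearing3 == "poor"
  hr[p] <- sample(c("poor", "very poor"), sum(p), replace = TRUE,
                  prob = c(0.7, 0.3))
  out$hearing_rating <- hr

  # alcohol fields (drive the normative-subsample NIAAA criterion)
  drinker <- stats::runif(n) < ifelse(true_status == "dementia", 0.15, 0.28)
  out$alcohol_days_week <- ifelse(drinker,
                                  sample(1:7, n, replace = TRUE,
                                         prob = c(0.30, 0.20, 0.15, 0.10,
                                                  0.10, 0.05, 0.10)), 0)
  out$alcohol_drinks_day <- ifelse(drinker,
                                   sample(1:5, n, replace = TRUE,
                                          prob = c(0.40, 0.30, 0.15, 0.10,
                                                   0.05)), 0)

  for (v in c("loneliness", "smoking")) {
    out[[v]] <- codebook_factor(lv[[v]], cb[[v]], v)
  }
  for (v in c("high_cholesterol", "diabetes", "retinopathy",
              "visual_impairment", "depression_diagnosis", "stroke",
              "alzheimer", "parkinson", "memory_complaint")) {
    out[[v]] <- factor(lv[[v]], levels = c("no", "yes"))
  }

  out <- plant_latent_cognition(out, params = list(
    battery_noise_sd = config$battery_noise_sd,
    label_noise = config$label_noise
  ))

  if (length(config$missingness_rates)) {
    out <- inject_missingness_impl(out, config$missingness_rates)
  }
  out
}

# log-odds contribution of each record under a latent-effects specification
latent_eta <- function(lv, life_satisfaction, effects, cb) {
  n <- length(life_satisfaction)
  eta <- numeric(n)
  for (v in names(effects)) {
    eff <- effects[[v]]
    if (v == "life_satisfaction") {
      eta <- eta + eff * (life_satisfaction - mean(life_satisfaction))
    } else if (length(eff) == 1 && is.null(names(eff))) {
      ref <- cb[[v]]$reference
      eta <- eta + eff * (lv[[v]] != ref)
    } else {
      contrib <- eff[lv[[v]]]
      contrib[is.na(contrib)] <- 0
      eta <- eta + unname(contrib)
    }
  }
  eta
}

# CES-D8 items realising a target published-keying score (0-8)
plant_cesd_items <- function(score) {
  n <- length(score)
  items <- matrix(0L, n, 8)
  yes_keyed <- c(1, 2, 3, 4, 6, 8)
  for (i in seq_len(n)) {
    pos <- sample.int(8, score[i])
    row <- integer(8)
    row[intersect(pos, yes_keyed)] <- 1L          # keyed "yes" answered yes
    row[setdiff(c(5, 7), pos)] <- 1L              # unkeyed reverse items: yes
    items[i, ] <- row
  }
  items
}

#' Plant battery, IADL and IQCODE responses for a given status
#'
#' Fills the cognition instruments so the derivation pipeline recovers the
#' planted status. A latent global cognition score is built as a linear
#' age/sex/education trend plus a planted individual deviation: records with
#' normal cognition draw deviations inside a band strictly above the -1.5
#' residual-SD cut, records with impairment or dementia draw deviations well
#' below it. The deviation distribution is deliberately gapped (no mass near
#' the cut) so that re-estimating the norms on the generated data cannot flip
#' a label when noise is zero. Battery completers with dementia also receive
#' difficulty in all four cognition-related IADLs; proxies receive 16 IQCODE
#' items whose mean lands in the category's scoring band.
#'
#' @param cohort data.frame with `true_status`, `proxy_flag`, `age_group`,
#'   `sex`, `education_level`.
#' @param params list: `battery_noise_sd` (Gaussian noise added to raw scores
#'   before rounding; default 0), `label_noise` (fraction planted under a
#'   random wrong status; default 0).
#' @return the cohort with battery, IADL and IQCODE columns filled.
#' @export
plant_latent_cognition <- function(cohort, params = list()) {
  noise_sd <- params$battery_noise_sd %||% 0
  label_noise <- params$label_noise %||% 0
  n <- nrow(cohort)
  cb <- default_codebook()
  status <- as.character(cohort$true_status)
  if (label_noise > 0) {
    flip <- which(stats::runif(n) < label_noise)
    for (i in flip) {
      status[i] <- sample(setdiff(c("normal", "impairment", "dementia"),
                                  status[i]), 1)
    }
  }
  proxy <- cohort$proxy_flag
  age <- unname(cb$age_group$map[as.character(cohort$age_group)])
  edu <- unname(cb$education_level$map[as.character(cohort$education_level)])
  female <- as.numeric(cohort$sex == "female")
  lin <- -0.03 * (age - 70) + 0.04 * (edu - 8) + 0.05 * female

  u <- stats::runif(n)
  sgn <- stats::runif(n) < 0.5
  delta <- ifelse(sgn, 1.5 + 0.5 * u, -(1.2 + 0.3 * u))
  low <- status != "normal"
  delta[low] <- -(4.2 + 1.2 * u[low])
  g <- lin + delta

  clampr <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)
  noise <- function() if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  ori_count <- clampr(3.4 + 0.30 * g + noise() * 0.30, 0, 4)
  sem <- clampr(4.5 + 0.55 * g + noise() * 0.55, 0, 6)
  flu <- clampr(13 + 2.6 * g + noise() * 2.6, 0, 30)
  imm <- clampr(5.5 + 1.0 * g + noise(), 0, 10)
  del <- clampr(4.5 + 1.0 * g + noise(), 0, 10)
  pro <- clampr(3.2 + 0.55 * g + noise() * 0.55, 0, 5)

  na_or <- function(x) ifelse(proxy, NA_real_, x)
  out <- cohort
  out$orientation_day <- na_or(as.numeric(ori_count >= 1))
  out$orientation_month <- na_or(as.numeric(ori_count >= 2))
  out$orientation_year <- na_or(as.numeric(ori_count >= 3))
  out$orientation_weekday <- na_or(as.numeric(ori_count >= 4))
  out$semantic_memory <- na_or(sem)
  out$fluency <- na_or(flu)
  out$immediate_recall <- na_or(imm)
  out$delayed_recall <- na_or(del)
  out$prospective <- na_or(pro)

  # IADL difficulties: all four for dementia; at most three otherwise
  count <- integer(n)
  dem <- status == "dementia"
  count[dem] <- 4L
  imp <- status == "impairment"
  count[imp] <- sample(0:3, sum(imp), replace = TRUE,
                       prob = c(0.30, 0.30, 0.25, 0.15))
  nrm <- status == "normal"
  count[nrm] <- sample(0:3, sum(nrm), replace = TRUE,
                       prob = c(0.75, 0.15, 0.07, 0.03))
  iadl <- matrix(0L, n, 4)
  for (i in which(count > 0)) iadl[i, sample.int(4, count[i])] <- 1L
  out$iadl_finances <- iadl[, 1]
  out$iadl_transport <- iadl[, 2]
  out$iadl_telephone <- iadl[, 3]
  out$iadl_medications <- iadl[, 4]

  # IQCODE items for proxies: 16-item sum landing in the category band
  s_target <- integer(n)
  s_target[nrm] <- sample(24:51, sum(nrm), replace = TRUE)
  s_target[imp] <- sample(52:55, sum(imp), replace = TRUE)
  s_target[dem] <- sample(57:75, sum(dem), replace = TRUE)
  iq <- matrix(NA_real_, n, 16)
  for (i in which(proxy)) {
    base <- s_target[i] %/% 16
    rem <- s_target[i] %% 16
    row <- rep(base, 16)
    if (rem > 0) row[sample.int(16, rem)] <- base + 1
    iq[i, ] <- row
  }
  for (j in 1:16) out[[sprintf("iqcode_%02d", j)]] <- iq[, j]
  out
}

#' Inject missing values completely at random
#'
#' Sets the raw columns of each named variable group to `NA` for a random
#' subset of records at the given rate. Group names follow
#' [default_missingness_rates()]; a name matching a single cohort column is
#' also accepted.
#'
#' @param cohort a cohort data.frame.
#' @param rates named numeric vector of rates in \[0, 1).
#' @param seed RNG seed for the masks.
#' @return the cohort with missing markers injected.
#' @export
inject_missingness <- function(cohort, rates = default_missingness_rates(),
                               seed = NULL) {
  assert_that(all(rates >= 0), "missingness rates must be non-negative")
  if (any(rates >= 1)) stop_cfg("missingness rate >= 1 for: %s",
                                paste(names(rates)[rates >= 1], collapse = ", "))
  with_seed(seed, inject_missingness_impl(cohort, rates))
}

inject_missingness_impl <- function(cohort, rates) {
  groups <- missingness_groups()
  n <- nrow(cohort)
  for (nm in names(rates)) {
    if (rates[[nm]] <= 0) next
    cols <- groups[[nm]] %||% nm
    missing_cols <- setdiff(cols, names(cohort))
    if (length(missing_cols)) {
      stop_cfg("unknown missingness target '%s' (no column %s)",
               nm, paste(missing_cols, collapse = ", "))
    }
    mask <- stats::runif(n) < rates[[nm]]
    for (cl in cols) cohort[[cl]][mask] <- NA
    if (nm == "hgs") cohort$hgs_inability[mask] <- FALSE
  }
  cohort
}

#' Write / read a cohort as CSV
#'
#' Plain-text round trip with empty cells as the missing marker.
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the cohort.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  cb <- default_codebook()
  for (v in intersect(names(cb), names(df))) {
    if (cb[[v]]$type != "numeric") {
      df[[v]] <- codebook_factor(df[[v]], cb[[v]], v)
    }
  }
  if ("true_status" %in% names(df)) {
    df$true_status <- factor(df$true_status,
                             levels = c("normal", "impairment", "dementia"))
  }
  for (v in c("visual_impairment", "depression_diagnosis", "stroke",
              "alzheimer", "parkinson", "memory_complaint")) {
    if (v %in% names(df)) df[[v]] <- factor(df[[v]], levels = c("no", "yes"))
  }
  df
}
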