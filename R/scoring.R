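#' Score the neuropsychological battery
#'
#' Produces per-subdomain raw scores from item responses: temporal orientation
#' (count of 4 correct binaries), semantic memory (count correct, 0-6),
#' semantic verbal fluency (animals named), immediate and delayed recall of a
#' 10-word list (0-10 each), and prospective memory (0-5).
#'
#' @param items a data.frame with columns `orientation_day`,
#'   `orientation_month`, `orientation_year`, `orientation_weekday` (0/1),
#'   `semantic_memory`, `fluency`, `immediate_recall`, `delayed_recall`,
#'   `prospective`.
#' @param semantic_max maximum semantic-memory item count (default 6).
#' @return data.frame with columns `orientation`, `semantic_memory`, `fluency`,
#'   `immediate_recall`, `delayed_recall`, `prospective`.
#' @export
#' @examples
#' it <- data.frame(orientation_day = 1, orientation_month = 1,
#'                  orientation_year = 1, orientation_weekday = 1,
#'                  semantic_memory = 5, fluency = 13, immediate_recall = 6,
#'                  delayed_recall = 4, prospective = 5)
#' score_battery(it)
score_battery <- function(items, semantic_max = 6) {
  need <- c("orientation_day", "orientation_month", "orientation_year",
            "orientation_weekday", "semantic_memory", "fluency",
            "immediate_recall", "delayed_recall", "prospective")
  miss <- setdiff(need, names(items))
  if (length(miss)) stop_cfg("battery items missing columns: %s",
                             paste(miss, collapse = ", "))
  ok01 <- function(x) all(is.na(x) | x %in% c(0, 1))
  ocols <- items[, c("orientation_day", "orientation_month",
                     "orientation_year", "orientation_weekday"), drop = FALSE]
  if (!all(vapply(ocols, ok01, logical(1)))) {
    stop_cfg("orientation items must be 0/1")
  }
  chk_range <- function(x, lo, hi, what) {
    if (any(!is.na(x) & (x < lo | x > hi))) {
      stop_cfg("%s out of range [%d, %d]", what, lo, hi)
    }
  }
  chk_range(items$semantic_memory, 0, semantic_max, "semantic memory score")
  chk_range(items$fluency, 0, Inf, "fluency count")
  chk_range(items$immediate_recall, 0, 10, "immediate recall (10-word list)")
  chk_range(items$delayed_recall, 0, 10, "delayed recall (10-word list)")
  chk_range(items$prospective, 0, 5, "prospective memory score")
  any_na <- Reduce(`|`, lapply(items[need], is.na))
  if (any(any_na)) {
    stop_cfg("battery items incomplete for %d record(s); battery scoring requires complete items",
             sum(any_na))
  }
  data.frame(
    orientation = rowSums(ocols),
    semantic_memory = items$semantic_memory,
    fluency = items$fluency,
    immediate_recall = items$immediate_recall,
    delayed_recall = items$delayed_recall,
    prospective = items$prospective
  )
}

#' Reference moments for battery z-standardisation
#'
#' Sample means and standard deviations per subdomain, estimated once on the
#' full battery-completer sample and reused to standardise any record.
#'
#' @param raw data.frame of raw scores from [score_battery()].
#' @return list with named numeric vectors `mean` and `sd`.
#' @export
battery_reference_stats <- function(raw) {
  m <- vapply(raw, mean, numeric(1))
  s <- vapply(raw, stats::sd, numeric(1))
  list(mean = m, sd = s)
}

#' Z-standardise battery raw scores and form the global cognitive score
#'
#' Each subdomain raw score is centred on the reference sample mean and scaled
#' by the reference sample standard deviation; the global cognitive score is
#' the arithmetic mean of the available subdomain z-scores.
#'
#' @param raw data.frame of raw scores from [score_battery()].
#' @param reference_stats list from [battery_reference_stats()]; if `NULL`,
#'   estimated from `raw` itself.
#' @return data.frame with one z column per subdomain (prefixed `z_`) plus
#'   `global_z`.
#' @export
standardize_battery <- function(raw, reference_stats = NULL) {
  ref <- reference_stats %||% battery_reference_stats(raw)
  zero <- names(ref$sd)[!is.na(ref$sd) & ref$sd == 0]
  if (length(zero)) {
    stop_cfg("zero reference SD for subdomain(s): %s",
             paste(zero, collapse = ", "))
  }
  z <- as.data.frame(mapply(function(col, m, s) (col - m) / s,
                            raw[names(ref$mean)], ref$mean, ref$sd,
                            SIMPLIFY = FALSE))
  names(z) <- paste0("z_", names(z))
  z$global_z <- rowMeans(z, na.rm = TRUE)
  z$global_z[!is.finite(z$global_z)] <- NA_real_
  z
}

#' Score the 16-item informant questionnaire (IQCODE)
#'
#' The score is the mean of the valid (answered) items, each on a 1-5 scale.
#' Categories: `normal` below 3.22, `impairment` in \[3.22, 3.48), `dementia`
#' at or above 3.48. The half-open upper boundary makes the three bands
#' exhaustive for non-integer means.
#'
#' @param items numeric vector of 16 items, or an n x 16 matrix/data.frame;
#'   `NA` marks unanswered items.
#' @param min_valid minimum number of answered items required (default 1).
#' @return data.frame with columns `iqcode_score` and `iqcode_category`
#'   (factor normal/impairment/dementia); both `NA` when fewer than
#'   `min_valid` items were answered.
#' @export
#' @examples
#' score_iqcode(rep(3, 16))          # 3.0 -> normal
#' score_iqcode(c(rep(4, 8), rep(NA, 8)))  # mean of valid items -> dementia
score_iqcode <- function(items, min_valid = 1) {
  if (is.null(dim(items))) items <- matrix(items, nrow = 1)
  items <- as.matrix(items)
  if (ncol(items) != 16) stop_cfg("IQCODE requires 16 items, got %d", ncol(items))
  if (any(!is.na(items) & !(items %in% 1:5))) {
    stop_cfg("IQCODE items must be integers in 1..5")
  }
  nvalid <- rowSums(!is.na(items))
  score <- rowMeans(items, na.rm = TRUE)
  score[nvalid < min_valid] <- NA_real_
  data.frame(iqcode_score = score,
             iqcode_category = iqcode_category(score))
}

#' @rdname score_iqcode
#' @param score numeric IQCODE score(s).
#' @export
iqcode_category <- function(score) {
  cat <- ifelse(is.na(score), NA_character_,
                ifelse(score < 3.22, "normal",
                       ifelse(score < 3.48, "impairment", "dementia")))
  factor(cat, levels = c("normal", "impairment", "dementia"))
}

#' Score the CES-D8 depressive-symptom scale
#'
#' Eight yes/no items covering the past week. Under the published keying,
#' items 1, 2, 3, 4, 6 and 8 score one point for "yes" and items 5 and 7 score
#' one point for "no"; a total of 4 or more flags depressive symptoms. The
#' published keying scores the positive-affect items (4 "felt happy",
#' 6 "enjoyed life") in the same direction as the negative items; set
#' `keying = "conventional"` for the usual reverse-keying of items 4 and 6.
#' Any missing item yields a missing score and flag.
#'
#' @param items 0/1 vector of 8 items (1 = "yes"), or an n x 8 matrix.
#' @param keying `"as_published"` (default) or `"conventional"`.
#' @return data.frame with columns `cesd_score` (0-8) and
#'   `depressive_symptoms` (`"yes"`/`"no"`).
#' @export
#' @examples
#' score_cesd8(rep(1, 8))  # all yes -> 6 under the published keying
score_cesd8 <- function(items, keying = c("as_published", "conventional")) {
  keying <- match.arg(keying)
  if (is.null(dim(items))) items <- matrix(items, nrow = 1)
  items <- as.matrix(items)
  if (ncol(items) != 8) stop_cfg("CES-D8 requires 8 items, got %d", ncol(items))
  if (any(!is.na(items) & !(items %in% c(0, 1)))) {
    stop_cfg("CES-D8 items must be 0/1")
  }
  no_keyed <- if (keying == "as_published") c(5, 7) else c(4, 5, 6, 7)
  pts <- items
  pts[, no_keyed] <- 1 - pts[, no_keyed]
  score <- rowSums(pts)
  data.frame(
    cesd_score = score,
    depressive_symptoms = factor(ifelse(is.na(score), NA_character_,
                                        ifelse(score >= 4, "yes", "no")),
                                 levels = c("no", "yes"))
  )
}

#' IPAQ total physical activity and categorical level
#'
#' Total physical activity (TPA) in MET-minutes/week weights each activity by
#' its energy cost: 3.3 for walking, 4.0 for moderate and 8.0 for vigorous
#' activity, multiplied by minutes per day and days per week, summed across
#' activities. The categorical level follows the standard three-level IPAQ
#' scoring algorithm:
#' \itemize{
#'   \item `high`: vigorous activity on 3+ days with TPA >= 1500, or any
#'     combination on 7+ days with TPA >= 3000;
#'   \item `moderate`: 3+ days of vigorous activity of 20+ minutes, or 5+ days
#'     of moderate activity or walking of 30+ minutes, or any combination on
#'     5+ days with TPA >= 600;
#'   \item `low`: otherwise.
#' }
#'
#' @param walk_days,walk_min,mod_days,mod_min,vig_days,vig_min days per week
#'   (0-7) and minutes per day (>= 0) for each activity; vectors recycle.
#' @return data.frame with columns `tpa` (MET-min/week) and `activity`
#'   (factor high/moderate/low, reference-ordered high first).
#' @export
#' @examples
#' ipaq_score(5, 30, 0, 0, 0, 0)  # 3.3 * 30 * 5 = 495 MET-min/week
ipaq_score <- function(walk_days, walk_min, mod_days, mod_min,
                       vig_days, vig_min) {
  args <- data.frame(walk_days, walk_min, mod_days, mod_min, vig_days, vig_min)
  if (any(!is.na(as.matrix(args)) & as.matrix(args) < 0)) {
    stop_cfg("IPAQ inputs must be non-negative")
  }
  for (d in c("walk_days", "mod_days", "vig_days")) {
    if (any(!is.na(args[[d]]) & args[[d]] > 7)) {
      stop_cfg("IPAQ days per week cannot exceed 7 (%s)", d)
    }
  }
  tpa <- 3.3 * args$walk_min * args$walk_days +
    4.0 * args$mod_min * args$mod_days +
    8.0 * args$vig_min * args$vig_days
  days_total <- args$walk_days + args$mod_days + args$vig_days
  high <- (args$vig_days >= 3 & tpa >= 1500) |
    (days_total >= 7 & tpa >= 3000)
  moderate <- (args$vig_days >= 3 & args$vig_min >= 20) |
    (args$mod_days >= 5 & args$mod_min >= 30) |
    (args$walk_days >= 5 & args$walk_min >= 30) |
    (days_total >= 5 & tpa >= 600)
  cat <- ifelse(is.na(tpa), NA_character_,
                ifelse(high, "high", ifelse(moderate, "moderate", "low")))
  data.frame(tpa = tpa,
             activity = factor(cat, levels = c("high", "moderate", "low")))
}

#' Synthetic handgrip-strength percentile norms
#'
#' Sex- and age-band-specific cut points at the 20th/40th/60th/80th
#' percentiles of absolute grip strength (kgf). The published study bands
#' strength against normative cut points given in supplementary material that
#' is not distributed with this package; this table is a synthetic stand-in
#' with the qualitative structure of adult dynamometry norms (men stronger
#' than women, monotone decline with age), intended for simulation and testing.
#'
#' @return data.frame with columns `sex`, `age_group`, `p20`, `p40`, `p60`,
#'   `p80` (kgf, strictly increasing within row).
#' @export
hgs_norms_synthetic <- function() {
  bands <- default_codebook()$age_group$levels
  idx <- seq_along(bands) - 1
  male <- data.frame(sex = "male", age_group = bands,
                     p20 = 33 - 1.8 * idx, p40 = 38 - 1.9 * idx,
                     p60 = 42 - 2.0 * idx, p80 = 47 - 2.1 * idx)
  female <- data.frame(sex = "female", age_group = bands,
                       p20 = 20 - 1.0 * idx, p40 = 23 - 1.05 * idx,
                       p60 = 26 - 1.1 * idx, p80 = 29 - 1.15 * idx)
  out <- rbind(male, female)
  rownames(out) <- NULL
  out
}

#' Band handgrip strength against sex/age percentile norms
#'
#' The summary value is the mean of the available trials (configurable to the
#' maximum); a flagged inability to perform the test scores 0 kgf. Bands:
#' `low` below the 20th percentile cut, `slightly_low` \[P20, P40),
#' `moderate` \[P40, P60), `slightly_high` \[P60, P80), `high` at or above the
#' P80 cut.
#'
#' @param trials numeric matrix/data.frame (n x up to 3) or vector of trial
#'   values in kgf; `NA` marks missing trials.
#' @param inability_flag logical: attempted but unable (scores 0).
#' @param sex,age_band character vectors matching the norms table levels.
#' @param norms norms table as from [hgs_norms_synthetic()].
#' @param summary `"mean"` (default) or `"max"` of available trials.
#' @return data.frame with `hgs_value` (kgf) and `hgs_band` (ordered factor,
#'   low..high); both `NA` when no trial is available and inability is not
#'   flagged (refusals are treated as missing).
#' @export
hgs_band <- function(trials, inability_flag, sex, age_band,
                     norms = hgs_norms_synthetic(),
                     summary = c("mean", "max")) {
  summary <- match.arg(summary)
  if (is.null(dim(trials))) trials <- matrix(trials, nrow = 1)
  trials <- as.matrix(trials)
  if (any(!is.na(trials) & trials < 0)) stop_cfg("HGS trials must be non-negative")
  if (!all(norms$p20 < norms$p40 & norms$p40 < norms$p60 &
           norms$p60 < norms$p80)) {
    stop_cfg("HGS norm cut points must be strictly increasing")
  }
  n <- nrow(trials)
  inability_flag <- rep_len(as.logical(inability_flag), n)
  sex <- rep_len(as.character(sex), n)
  age_band <- rep_len(as.character(age_band), n)
  value <- if (summary == "mean") {
    rowMeans(trials, na.rm = TRUE)
  } else {
    suppressWarnings(apply(trials, 1, max, na.rm = TRUE))
  }
  value[!is.finite(value)] <- NA_real_
  value[inability_flag] <- 0
  key <- paste(sex, age_band)
  nkey <- paste(norms$sex, norms$age_group)
  idx <- match(key, nkey)
  if (any(is.na(idx) & !is.na(value))) {
    stop_cfg("no HGS norms for: %s", paste(unique(key[is.na(idx)]), collapse = ", "))
  }
  cuts <- norms[idx, c("p20", "p40", "p60", "p80")]
  lev <- c("low", "slightly_low", "moderate", "slightly_high", "high")
  band <- ifelse(is.na(value), NA_integer_,
                 1L + (value >= cuts$p20) + (value >= cuts$p40) +
                   (value >= cuts$p60) + (value >= cuts$p80))
  data.frame(hgs_value = value,
             hgs_band = factor(lev[band], levels = lev))
}

#' Weekly alcohol intake and excess flags
#'
#' Weekly drinks = drinks per typical drinking day x drinking days per week.
#' The study flag marks 21+ drinks/week (168 g pure alcohol). The NIAAA flag
#' is sex-specific: men 14+ weekly or 4+ daily; women 7+ weekly or 3+ daily.
#'
#' @param drinks_per_day,days_per_week numeric vectors (days 0-7).
#' @param sex `"male"`/`"female"` vector for the NIAAA rule.
#' @return data.frame with `weekly_drinks`, `excessive_study`,
#'   `excessive_niaaa` (logicals, `NA` on missing input).
#' @export
alcohol_weekly <- function(drinks_per_day, days_per_week, sex) {
  if (any(!is.na(days_per_week) & (days_per_week < 0 | days_per_week > 7))) {
    stop_cfg("days_per_week must be in 0..7")
  }
  if (any(!is.na(drinks_per_day) & drinks_per_day < 0)) {
    stop_cfg("drinks_per_day must be non-negative")
  }
  weekly <- drinks_per_day * days_per_week
  male <- rep_len(as.character(sex) == "male", length(weekly))
  niaaa <- ifelse(male, weekly >= 14 | drinks_per_day >= 4,
                  weekly >= 7 | drinks_per_day >= 3)
  data.frame(weekly_drinks = weekly,
             excessive_study = weekly >= 21,
             excessive_niaaa = niaaa)
}

#' Body mass index and WHO band
#'
#' BMI = weight (kg) / height (m)^2, banded as: severely underweight < 16.0;
#' underweight \[16.0, 18.5); normal weight \[18.5, 25.0); overweight
#' \[25.0, 30.0); obese grade I \[30.0, 35.0); grade II \[35.0, 40.0);
#' grade III >= 40.0. The half-open bands partition the positive axis.
#'
#' @param weight_kg,height_m positive numeric vectors.
#' @return data.frame with `bmi` and `bmi_band` (ordered factor).
#' @export
#' @examples
#' bmi_band(70, 1.75)
bmi_band <- function(weight_kg, height_m) {
  if (any(!is.na(weight_kg) & weight_kg <= 0) ||
      any(!is.na(height_m) & height_m <= 0)) {
    stop_cfg("weight and height must be positive")
  }
  bmi <- weight_kg / height_m^2
  lev <- c("severely_underweight", "underweight", "normal_weight",
           "overweight", "obese_1", "obese_2", "obese_3")
  cut <- c(16, 18.5, 25, 30, 35, 40)
  idx <- ifelse(is.na(bmi), NA_integer_,
                1L + rowSums(outer(bmi, cut, `>=`)))
  data.frame(bmi = bmi, bmi_band = factor(lev[idx], levels = lev))
}

#' Social-isolation flag from three contact-frequency items
#'
#' A participant is socially isolated when every answered item (in-person
#' contact with children, relatives, friends) is less frequent than monthly.
#' A single answered item suffices for classification; the result is missing
#' only when all three items are missing.
#'
#' @param children_freq,relatives_freq,friends_freq character vectors on the
#'   six-level frequency scale from [contact_levels()].
#' @return factor vector `"no"`/`"yes"` (`NA` when all items missing).
#' @export
social_isolation <- function(children_freq, relatives_freq, friends_freq) {
  lv <- contact_levels()
  to_idx <- function(x) {
    x <- as.character(x)
    bad <- !is.na(x) & !(x %in% lv)
    if (any(bad)) stop_cfg("unknown contact frequency level: %s",
                           paste(unique(x[bad]), collapse = ", "))
    match(x, lv)
  }
  m <- cbind(to_idx(children_freq), to_idx(relatives_freq),
             to_idx(friends_freq))
  answered <- rowSums(!is.na(m))
  monthly_plus <- rowSums(!is.na(m) & m <= 3) > 0
  out <- ifelse(answered == 0, NA_character_,
                ifelse(monthly_plus, "no", "yes"))
  factor(out, levels = c("no", "yes"))
}

#' Six-level contact-frequency scale
#'
#' Levels 1-3 are at least monthly; levels 4-6 are less than monthly.
#' @return character vector of the six levels, most frequent first.
#' @export
contact_levels <- function() {
  c("3+ times per week", "1-2 times per week", "1-2 times per month",
    "every 2-3 months", "once or twice per year", "less than once a year")
}

#' Recode the five-level hearing self-rating to three levels
#'
#' "very good or excellent" and "good" map to `good`; "fair" to `fair`;
#' "poor" and "very poor" to `poor`. Missing passes through.
#'
#' @param rating character vector on the five-level scale.
#' @return factor vector good/fair/poor.
#' @export
hearing_recode <- function(rating) {
  map <- c("very good or excellent" = "good", "good" = "good",
           "fair" = "fair", "poor" = "poor", "very poor" = "poor")
  rating <- as.character(rating)
  bad <- !is.na(rating) & !(rating %in% names(map))
  if (any(bad)) stop_cfg("unknown hearing rating: %s",
                         paste(unique(rating[bad]), collapse = ", "))
  factor(unname(map[rating]), levels = c("good", "fair", "poor"))
}

#' Score a whole cohort
#'
#' Applies every instrument scorer to the raw cohort columns and appends the
#' derived analysis variables: battery raw and z scores with the global
#' cognitive score (battery completers only), IQCODE score/category, CES-D8
#' score and depressive-symptom flag, IPAQ TPA and activity level, handgrip
#' value and band, weekly alcohol and excess flags, BMI and band, social
#' isolation, three-level hearing, IADL difficulty count, and the numeric
#' covariates for the norm regression (`age_years`, `education_years`,
#' `sex01`).
#'
#' @param cohort a cohort data.frame from [generate_cohort()] (or real data in
#'   the same layout).
#' @param codebook predictor codebook.
#' @param hgs_norms handgrip norms table.
#' @param cesd_keying passed to [score_cesd8()].
#' @param hgs_summary passed to [hgs_band()].
#' @return the cohort with derived columns appended (class `cogstatus_scored`).
#' @export
score_cohort <- function(cohort, codebook = default_codebook(),
                         hgs_norms = hgs_norms_synthetic(),
                         cesd_keying = "as_published",
                         hgs_summary = "mean") {
  df <- cohort
  n <- nrow(df)
  battery_cols <- c("orientation_day", "orientation_month", "orientation_year",
                    "orientation_weekday", "semantic_memory", "fluency",
                    "immediate_recall", "delayed_recall", "prospective")
  non_proxy <- !df$proxy_flag
  raw_names <- c("orientation", "semantic_memory_raw", "fluency_raw",
                 "immediate_raw", "delayed_raw", "prospective_raw")
  for (nm in c("orientation", "global_z")) df[[nm]] <- NA_real_
  if (any(non_proxy)) {
    raw <- score_battery(df[non_proxy, battery_cols])
    ref <- battery_reference_stats(raw)
    z <- standardize_battery(raw, ref)
    df$orientation[non_proxy] <- raw$orientation
    df$global_z[non_proxy] <- z$global_z
    attr(df, "battery_reference") <- ref
  }
  iq_cols <- sprintf("iqcode_%02d", 1:16)
  iq <- score_iqcode_allow_empty(as.matrix(df[, iq_cols]))
  df$iqcode_score <- iq$iqcode_score
  df$iqcode_category <- iq$iqcode_category
  cesd <- score_cesd8(as.matrix(df[, sprintf("cesd_%d", 1:8)]),
                      keying = cesd_keying)
  df$cesd_score <- cesd$cesd_score
  df$depressive_symptoms <- cesd$depressive_symptoms
  ip <- ipaq_score(df$ipaq_walk_days, df$ipaq_walk_min, df$ipaq_mod_days,
                   df$ipaq_mod_min, df$ipaq_vig_days, df$ipaq_vig_min)
  df$tpa <- ip$tpa
  df$activity <- ip$activity
  hg <- hgs_band(df[, c("hgs_trial1", "hgs_trial2", "hgs_trial3")],
                 df$hgs_inability, df$sex, df$age_group, norms = hgs_norms,
                 summary = hgs_summary)
  df$hgs_value <- hg$hgs_value
  df$hgs_band <- hg$hgs_band
  al <- alcohol_weekly(df$alcohol_drinks_day, df$alcohol_days_week, df$sex)
  df$weekly_drinks <- al$weekly_drinks
  df$excessive_study <- al$excessive_study
  df$excessive_niaaa <- al$excessive_niaaa
  bm <- bmi_band(df$weight_kg, df$height_m)
  df$bmi <- bm$bmi
  df$bmi_band <- bm$bmi_band
  df$social_isolation <- social_isolation(df$contact_children,
                                          df$contact_relatives,
                                          df$contact_friends)
  df$hearing3 <- hearing_recode(df$hearing_rating)
  df$iadl_count <- rowSums(df[, c("iadl_finances", "iadl_transport",
                                  "iadl_telephone", "iadl_medications")])
  df$age_years <- unname(codebook$age_group$map[as.character(df$age_group)])
  df$education_years <-
    unname(codebook$education_level$map[as.character(df$education_level)])
  df$sex01 <- as.integer(df$sex == "female")
  class(df) <- c("cogstatus_scored", class(cohort))
  df
}

# IQCODE scoring that returns NA rows (instead of erroring) when a record has
# no informant assessment at all (battery completers)
score_iqcode_allow_empty <- function(items) {
  nvalid <- rowSums(!is.na(items))
  out <- data.frame(iqcode_score = rep(NA_real_, nrow(items)),
                    iqcode_category = iqcode_category(rep(NA_real_, nrow(items))))
  if (any(nvalid > 0)) {
    sc <- score_iqcode(items[nvalid > 0, , drop = FALSE])
    out$iqcode_score[nvalid > 0] <- sc$iqcode_score
    out$iqcode_category[nvalid > 0] <- sc$iqcode_category
  }
  out
}
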