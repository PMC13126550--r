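#' Default predictor codebook
#'
#' The codebook declares, for every candidate predictor and auxiliary variable,
#' its measurement type (`ordinal`, `nominal`, `binary`, `numeric`), the ordered
#' level set, the reference level used in odds-ratio models, and the numeric
#' maps needed by the norm regression (years of schooling per education level,
#' midpoint age per 5-year band).
#'
#' Reference levels follow the survey convention: highest education, youngest
#' age band, male, white skin colour, married, normal weight, high handgrip
#' strength, high physical activity, good hearing, never lonely, and the "no"
#' level of each binary indicator.
#'
#' @return an object of class `cogstatus_codebook`: a named list with one entry
#'   per variable, each a list with elements `type`, `levels`, `reference`, and
#'   optionally `map` (named numeric) or `range`.
#' @export
#' @examples
#' cb <- default_codebook()
#' names(cb)
#' cb$education_level$map
default_codebook <- function() {
  ord <- function(levels, reference, map = NULL) {
    list(type = "ordinal", levels = levels, reference = reference, map = map)
  }
  nom <- function(levels, reference) {
    list(type = "nominal", levels = levels, reference = reference)
  }
  bin <- function(reference = "no") {
    list(type = "binary", levels = c("no", "yes"), reference = reference)
  }
  cb <- list(
    education_level = ord(
      c("illiterate", "less_than_primary", "completed_primary",
        "incomplete_secondary", "completed_secondary", "higher_education"),
      reference = "higher_education",
      map = c(illiterate = 0, less_than_primary = 4, completed_primary = 8,
              incomplete_secondary = 10, completed_secondary = 11,
              higher_education = 15)
    ),
    age_group = ord(
      c("50-54", "55-59", "60-64", "65-69", "70-74", "75-79", "80-84",
        "85-89", "90+"),
      reference = "50-54",
      map = c("50-54" = 52, "55-59" = 57, "60-64" = 62, "65-69" = 67,
              "70-74" = 72, "75-79" = 77, "80-84" = 82, "85-89" = 87,
              "90+" = 92)
    ),
    sex = list(type = "binary", levels = c("male", "female"),
               reference = "male"),
    occupation_30d = bin(),
    marital_status = nom(
      c("single", "married", "divorced_separated", "widowed"),
      reference = "married"
    ),
    skin_color = nom(
      c("white", "black", "brown", "yellow", "indigenous"),
      reference = "white"
    ),
    life_satisfaction = list(type = "numeric", range = c(1, 10),
                             rescale = TRUE),
    bmi_band = ord(
      c("severely_underweight", "underweight", "normal_weight", "overweight",
        "obese_1", "obese_2", "obese_3"),
      reference = "normal_weight"
    ),
    hgs_band = ord(
      c("low", "slightly_low", "moderate", "slightly_high", "high"),
      reference = "high"
    ),
    activity = ord(c("high", "moderate", "low"), reference = "high"),
    loneliness = ord(c("never", "sometimes", "always"), reference = "never"),
    hearing3 = ord(c("good", "fair", "poor"), reference = "good"),
    depressive_symptoms = bin(),
    high_cholesterol = bin(),
    diabetes = bin(),
    smoking = ord(c("no", "less_than_daily", "daily"), reference = "no"),
    social_isolation = bin(),
    retinopathy = bin()
  )
  structure(cb, class = "cogstatus_codebook")
}

#' Names of the candidate predictors
#'
#' @param codebook a codebook from [default_codebook()].
#' @return character vector of the 18 candidate predictor names, in codebook
#'   (column) order.
#' @export
predictor_names <- function(codebook = default_codebook()) {
  names(codebook)
}

#' Write / read a codebook as JSON
#'
#' @param codebook a `cogstatus_codebook`.
#' @param path file path.
#' @return `write_codebook` returns `path` invisibly; `read_codebook` returns
#'   the codebook.
#' @export
write_codebook <- function(codebook, path) {
  jsonlite::write_json(unclass(codebook), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  cb <- jsonlite::read_json(path, simplifyVector = TRUE)
  cb <- lapply(cb, function(e) {
    if (!is.null(e$map)) e$map <- unlist(e$map)
    e
  })
  structure(cb, class = "cogstatus_codebook")
}

# coerce a character column to the codebook factor, validating levels
codebook_factor <- function(x, entry, name) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% entry$levels)
  if (any(bad)) {
    stop_cfg("variable '%s' has values outside codebook levels: %s",
             name, paste(unique(x[bad]), collapse = ", "))
  }
  factor(x, levels = entry$levels)
}
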