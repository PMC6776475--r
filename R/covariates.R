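#' Week-weighted daily hours from weekday and weekend reports
#'
#' Weekday and weekend durations are combined with weights 5/7 and 2/7,
#' the number of weekdays and weekend days per week.
#'
#' @param weekday_h,weekend_h Hours per day; both must be non-negative.
#' @return Hours per day.
#' @export
#' @examples
#' weekly_weighted_hours(0.7, 1.4) # 0.9
weekly_weighted_hours <- function(weekday_h, weekend_h) {
  if (any(weekday_h < 0, na.rm = TRUE) || any(weekend_h < 0, na.rm = TRUE)) {
    stop("durations must be non-negative", call. = FALSE)
  }
  weekday_h * 5 / 7 + weekend_h * 2 / 7
}

#' Total daily sleep: nursery-school nap plus night-time sleep
#' @param nap_h,night_h Hours per day, non-negative.
#' @return Hours per day.
#' @export
total_sleep <- function(nap_h, night_h) {
  if (any(nap_h < 0, na.rm = TRUE) || any(night_h < 0, na.rm = TRUE)) {
    stop("durations must be non-negative", call. = FALSE)
  }
  nap_h + night_h
}

#' Categorise a value at left-closed cutpoints
#'
#' Intervals are closed on the left exactly as category labels of the form
#' ">= x" read: a value equal to a cutpoint goes to the higher category.
#'
#' @param value Numeric vector.
#' @param cutpoints Increasing numeric cutpoints.
#' @param labels Category labels, `length(cutpoints) + 1` of them, ordered
#'   low to high.
#' @return Factor with the given labels (ordered by construction).
#' @export
#' @examples
#' categorize(c(0.4, 0.5, 1.2), c(0.5, 1), c("<0.5", ">=0.5 to <1", ">=1"))
categorize <- function(value, cutpoints, labels) {
  stopifnot(length(labels) == length(cutpoints) + 1L,
            !is.unsorted(cutpoints, strictly = TRUE))
  idx <- findInterval(value, cutpoints, left.open = FALSE) + 1L
  factor(labels[idx], levels = labels)
}

#' Adult weight status from BMI
#'
#' Underweight below 18.5 kg/m2, normal from 18.5 to below 25, overweight
#' and obese at 25 and above.
#'
#' @param bmi Body mass index, kg/m2; positive.
#' @return Factor: `Underweight`, `Normal`, `Overweight and obese`.
#' @export
adult_weight_status <- function(bmi) {
  if (any(bmi <= 0, na.rm = TRUE)) stop("bmi must be positive", call. = FALSE)
  categorize(bmi, c(18.5, 25), c("Underweight", "Normal", "Overweight and obese"))
}

#' Child weight status from age- and sex-specific BMI cutoffs
#'
#' Child BMI thresholds that map to the adult 18.5 and 25 kg/m2 boundaries
#' depend on age and sex and are supplied as a lookup table (the package
#' ships a synthetic stand-in; substitute the published cutoff table for
#' real analyses). The upper boundary is inclusive, matching the adult
#' ">= 25" convention.
#'
#' @param bmi Body mass index, kg/m2.
#' @param age_years Age in completed years.
#' @param sex `"Boys"` or `"Girls"`.
#' @param cutoff_table Data frame with columns `age_years`, `sex`,
#'   `bmi_lower` (maps to adult 18.5) and `bmi_upper` (maps to adult 25).
#' @return Factor as in [adult_weight_status()].
#' @export
child_weight_status <- function(bmi, age_years, sex, cutoff_table) {
  key <- paste(age_years, sex)
  tab_key <- paste(cutoff_table$age_years, cutoff_table$sex)
  m <- match(key, tab_key)
  if (anyNA(m)) {
    stop("no BMI cutoffs for age/sex: ",
         paste(unique(key[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  lower <- cutoff_table$bmi_lower[m]
  upper <- cutoff_table$bmi_upper[m]
  lab <- ifelse(bmi < lower, "Underweight",
                ifelse(bmi >= upper, "Overweight and obese", "Normal"))
  factor(lab, levels = c("Underweight", "Normal", "Overweight and obese"))
}

#' Path to the synthetic child BMI cutoff table shipped with the package
#'
#' A smooth, plausible stand-in for published age- and sex-specific child
#' BMI cutoffs (it is *not* the published table, which is not
#' redistributable); use only for simulation and testing.
#'
#' @return File path of the CSV.
#' @export
synthetic_child_bmi_cutoffs <- function() {
  system.file("extdata", "child_bmi_cutoffs_synthetic.csv",
              package = "freesugar", mustWork = TRUE)
}

#' Equivalised household income tertile
#'
#' Annual household income is adjusted for household size and composition
#' by an equivalence scale (default: square root of household size) and
#' bucketed at the tertile cutpoints 2,380,000 and 3,340,000 yen/year
#' (boundaries inclusive upward).
#'
#' @param income Annual household income, yen/year; non-negative.
#' @param household_size Number of household members; at least 1.
#' @param scale Function mapping household size to the equivalence divisor.
#' @param cutpoints Two increasing cutpoints on the equivalised scale.
#' @return Factor: `Low`, `Middle`, `High`.
#' @export
#' @examples
#' equivalized_income_tertile(4e6, 4) # 4e6 / 2 = 2e6 -> Low
equivalized_income_tertile <- function(income, household_size,
                                       scale = sqrt,
                                       cutpoints = c(2380000, 3340000)) {
  if (any(income < 0, na.rm = TRUE)) stop("income must be non-negative", call. = FALSE)
  if (any(household_size < 1, na.rm = TRUE)) {
    stop("household_size must be at least 1", call. = FALSE)
  }
  categorize(income / scale(household_size), cutpoints, c("Low", "Middle", "High"))
}

#' Derive the categorical covariates used by the association analysis
#'
#' Maps raw questionnaire-style fields of a cohort table to the categorical
#' encodings of the association analysis: week-weighted screen time and
#' outdoor playtime, total sleep, child and parental weight status, and the
#' equivalised income tertile. Reference levels are set to the conventions
#' of the analysis (boys, age 3, normal weight, short sleep, lowest
#' activity/screen/income category, professional/managerial occupation,
#' non-smoking, no grandparents, no siblings).
#'
#' Expected raw columns: `child_id`, `sex`, `age_years`, `height_cm`,
#' `weight_kg`, `nap_h`, `night_sleep_h`, `outdoor_weekday_h`,
#' `outdoor_weekend_h`, `screen_weekday_h`, `screen_weekend_h`;
#' `maternal_age_years`, `maternal_height_cm`, `maternal_weight_kg`,
#' `maternal_education_years`, `maternal_occupation`, `maternal_smoking`;
#' the corresponding `paternal_*` columns; `lives_with_grandparents`,
#' `n_siblings`, `household_income_yen`, `household_size`.
#'
#' @param raw Cohort table of raw fields (see Details).
#' @param child_bmi_cutoffs Cutoff table for [child_weight_status()].
#' @param income_scale Equivalence scale function for
#'   [equivalized_income_tertile()].
#' @return Tibble of factors, one row per child, with `child_id` first;
#'   rows with any missing derived covariate are dropped (complete-case
#'   analysis) with a message.
#' @export
derive_covariates <- function(raw,
                              child_bmi_cutoffs = readr::read_csv(
                                synthetic_child_bmi_cutoffs(),
                                show_col_types = FALSE),
                              income_scale = sqrt) {
  occ_levels <- c("Professional and manager", "Office work, service, and sales",
                  "Manual", "Unemployed")
  bmi <- function(w, h) w / (h / 100)^2
  out <- tibble::tibble(
    child_id = raw$child_id,
    sex = factor(raw$sex, levels = c("Boys", "Girls")),
    age = factor(raw$age_years, levels = 3:6),
    weight_status = child_weight_status(bmi(raw$weight_kg, raw$height_cm),
                                        raw$age_years, raw$sex,
                                        child_bmi_cutoffs),
    sleep = categorize(total_sleep(raw$nap_h, raw$night_sleep_h),
                       10, c("<10", ">=10")),
    outdoor = categorize(weekly_weighted_hours(raw$outdoor_weekday_h,
                                               raw$outdoor_weekend_h),
                         c(1, 2), c("<1", ">=1 to <2", ">=2")),
    screen = categorize(weekly_weighted_hours(raw$screen_weekday_h,
                                              raw$screen_weekend_h),
                        c(0.5, 1), c("<0.5", ">=0.5 to <1", ">=1")),
    maternal_age = categorize(raw$maternal_age_years, c(30, 40),
                              c("20 to 29", "30 to 39", ">=40")),
    maternal_weight_status = adult_weight_status(
      bmi(raw$maternal_weight_kg, raw$maternal_height_cm)),
    maternal_education = categorize(raw$maternal_education_years, c(13, 15),
                                    c("<=12", "13 to 14", ">=15")),
    maternal_occupation = factor(raw$maternal_occupation, levels = occ_levels),
    maternal_smoking = factor(ifelse(raw$maternal_smoking, "Yes", "No"),
                              levels = c("No", "Yes")),
    paternal_age = categorize(raw$paternal_age_years, c(30, 40),
                              c("20 to 29", "30 to 39", ">=40")),
    paternal_weight_status = adult_weight_status(
      bmi(raw$paternal_weight_kg, raw$paternal_height_cm)),
    paternal_education = categorize(raw$paternal_education_years, c(13, 15),
                                    c("<=12", "13 to 14", ">=15")),
    paternal_occupation = factor(raw$paternal_occupation, levels = occ_levels),
    paternal_smoking = factor(ifelse(raw$paternal_smoking, "Yes", "No"),
                              levels = c("No", "Yes")),
    grandparents = factor(ifelse(raw$lives_with_grandparents, "Yes", "No"),
                          levels = c("No", "Yes")),
    siblings = categorize(raw$n_siblings, c(1, 2), c("0", "1", ">=2")),
    income = equivalized_income_tertile(raw$household_income_yen,
                                        raw$household_size,
                                        scale = income_scale)
  )
  # weight_status reference is "Normal", not the lowest-ordered level
  out$weight_status <- stats::relevel(out$weight_status, ref = "Normal")
  out$maternal_weight_status <- stats::relevel(out$maternal_weight_status,
                                               ref = "Normal")
  out$paternal_weight_status <- stats::relevel(out$paternal_weight_status,
                                               ref = "Normal")
  complete <- stats::complete.cases(out)
  if (!all(complete)) {
    message(sum(!complete), " row(s) with missing covariates dropped ",
            "(complete-case analysis)")
    out <- out[complete, ]
  }
  out
}
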