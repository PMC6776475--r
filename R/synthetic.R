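#' Configuration for the synthetic study generator
#'
#' Defaults reproduce the design of the motivating survey: 332 children
#' (166 of each sex; 87/86/85/74 children aged 3/4/5/6), covariate
#' marginals taken from the published category counts
#' ([reference_cohort_counts()]), a multivariable outcome model whose
#' log-odds-ratios default to the published adjusted odds ratios (0 where
#' undefined), energy intake around 1371 (SD 231) kcal/d, and free sugar
#' supplying on average 7.8% (SD 3.2%) of energy, modelled as a gamma
#' distribution (right-skewed and positive; the survey reports only the
#' mean and SD). The logistic intercept is calibrated so the
#' cohort-average excessive probability equals the gamma tail mass above
#' the 10%-of-energy threshold (about 22%), which keeps the conditional
#' sampling of percent-energy given the latent flag distortion-free.
#'
#' @param n_children Cohort size.
#' @param sex_counts,age_counts Named integer targets; used exactly when
#'   they sum to `n_children`, as sampling proportions otherwise.
#' @param reference Marginals/effects table in the layout of
#'   [reference_cohort_counts()].
#' @param energy_mean,energy_sd,energy_range Daily energy target
#'   distribution, kcal/d (normal, truncated to `energy_range`).
#' @param pct_mean,pct_sd Free sugar percent-of-energy target mean/SD
#'   (gamma, moment-matched).
#' @param pct_range Support truncation of the percent-energy distribution.
#' @param threshold Excessive-intake threshold, percent of energy.
#' @param n_extra_per_group Random filler foods added to each staple food
#'   group of the synthetic composition table.
#' @param staples_per_day,sugary_per_day Foods sampled per recorded day.
#' @param sugary_group_weights Sampling weights of the sugar-dense groups.
#' @param log_or Optional named list overriding the generating
#'   log-odds-ratios, e.g. `list(screen = c(">=1" = log(4.36)))`; set all
#'   to zero for a null model via `log_or = "null"`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_children = 332,
                       sex_counts = c(Boys = 166, Girls = 166),
                       age_counts = c(`3` = 87, `4` = 86, `5` = 85, `6` = 74),
                       reference = reference_cohort_counts(),
                       energy_mean = 1371, energy_sd = 231,
                       energy_range = c(700, 2200),
                       pct_mean = 7.8, pct_sd = 3.2,
                       pct_range = c(1.5, 25),
                       threshold = 10,
                       n_extra_per_group = 2,
                       staples_per_day = 7,
                       sugary_per_day = 3,
                       sugary_group_weights = c(
                         "Confectionaries" = 0.45,
                         "Sugar-sweetened beverages" = 0.25,
                         "Sugars and jams" = 0.17,
                         "Fruit and vegetable juices" = 0.13),
                       log_or = NULL) {
  stopifnot(n_children >= 2, pct_mean > 0, pct_sd > 0,
            pct_range[1] < threshold, threshold < pct_range[2])
  shape <- (pct_mean / pct_sd)^2
  rate <- pct_mean / pct_sd^2
  if (pct_mean <= pct_range[1] || pct_mean >= pct_range[2]) {
    stop("infeasible calibration: pct_mean outside pct_range", call. = FALSE)
  }
  vars <- setdiff(unique(reference$variable), c("sex", "age"))
  marginals <- lapply(stats::setNames(vars, vars), function(v) {
    sub <- reference[reference$variable == v, ]
    stats::setNames(sub$n_total / sum(sub$n_total), sub$category)
  })
  lo <- lapply(stats::setNames(unique(reference$variable),
                               unique(reference$variable)), function(v) {
    sub <- reference[reference$variable == v, ]
    b <- ifelse(sub$reference | is.na(sub$adj_or), 0, log(sub$adj_or))
    stats::setNames(b, sub$category)
  })
  if (identical(log_or, "null")) {
    lo <- lapply(lo, function(b) b * 0)
  } else if (!is.null(log_or)) {
    for (v in names(log_or)) lo[[v]][names(log_or[[v]])] <- log_or[[v]]
  }
  structure(list(
    n_children = n_children, sex_counts = sex_counts, age_counts = age_counts,
    marginals = marginals, log_or = lo,
    energy_mean = energy_mean, energy_sd = energy_sd,
    energy_range = energy_range,
    pct_mean = pct_mean, pct_sd = pct_sd, pct_range = pct_range,
    threshold = threshold,
    gamma_shape = shape, gamma_rate = rate,
    prevalence_target = 1 - stats::pgamma(threshold, shape, rate),
    n_extra_per_group = n_extra_per_group,
    staples_per_day = staples_per_day, sugary_per_day = sugary_per_day,
    sugary_group_weights = sugary_group_weights
  ), class = "sim_config")
}

# truncated distributions via inverse CDF (deterministic given the RNG)
rtrunc_gamma <- function(n, shape, rate, lo, hi) {
  u <- stats::runif(n, stats::pgamma(lo, shape, rate),
                    stats::pgamma(hi, shape, rate))
  stats::qgamma(u, shape, rate)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# sample exact counts when they add up to n, otherwise by proportion
sample_categories <- function(n, counts) {
  if (sum(counts) == n) {
    sample(rep(names(counts), counts))
  } else {
    sample(names(counts), n, replace = TRUE, prob = counts / sum(counts))
  }
}

#' Generate the synthetic ground-truthed food composition table
#'
#' Produces a curated food table spanning all 10 food groups in which, by
#' construction, at least one item forces each total-sugar step (1--7) and
#' each added/free step (1--11): items carry full saccharide profiles,
#' all-sugar flags, literature values, raw-form and similar-item links,
#' foreign-table values (with monosaccharide-equivalent disaccharides),
#' recipes, unsweetened counterparts, sweetened-dairy lactose, processed
#' flags, or nothing at all. Hidden ground-truth assignments (values and
#' step provenance, computed from the construction itself) are returned
#' alongside for oracle testing. Optional random filler foods (full
#' saccharide data, no added sugar) pad the staple groups.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @return List: `food_table` (input table for [build_sugar_db()]) and
#'   `truth` (tibble: `food_code`, `true_total`, `true_added`,
#'   `true_free`, `true_total_step`, `true_free_step`).
#' @export
gen_food_db <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- food_groups()
  base <- tibble::tribble(
    ~food_code, ~name, ~food_group,
    ~protein, ~fat, ~saturated_fat, ~carbohydrate, ~dietary_fiber, ~water,
    ~glucose, ~fructose, ~galactose, ~sucrose, ~lactose, ~maltose,
    "CER1", "cooked rice",        g[1], 2.5, 0.3, 0.1, 37.0, 1.5, 60.0, 0.1, 0.0, 0.0, 0.0, 0.0, 0.2,
    "CER2", "white bread",        g[1], 9.0, 4.0, 1.8, 46.0, 2.3, 39.0, 0.6, 0.6, 0.0, 1.0, 0.3, 1.5,
    "CER3", "raw rice",           g[1], 6.0, 0.9, 0.3, 77.0, 0.5, 15.0, 0.1, 0.0, 0.0, 0.1, 0.0, 0.5,
    "CER4", "rice porridge",      g[1], 1.1, 0.1, 0.0, 16.0, 0.2, 83.0,  NA,  NA,  NA,  NA,  NA,  NA,
    "CER5", "boiled potato",      g[1], 1.5, 0.1, 0.0, 18.0, 1.6, 79.0, 0.3, 0.2, 0.0, 0.2, 0.0, 0.0,
    "CER6", "boiled noodles",     g[1], 5.0, 0.6, 0.2, 26.0, 1.2, 67.0,  NA,  NA,  NA,  NA,  NA,  NA,
    "SUG1", "granulated sugar",   g[2], 0.0, 0.0, 0.0, 99.9, 0.0,  0.5,  NA,  NA,  NA,  NA,  NA,  NA,
    "SUG2", "strawberry jam",     g[2], 0.4, 0.1, 0.0, 62.0, 1.0, 36.0, 10.0, 12.0, 0.0, 24.0, 0.0, 1.0,
    "SUG3", "honey",              g[2], 0.3, 0.0, 0.0, 81.9, 0.0, 17.6,  NA,  NA,  NA,  NA,  NA,  NA,
    "SUG4", "maple syrup",        g[2], 0.0, 0.0, 0.0, 66.3, 0.0, 33.0,  NA,  NA,  NA,  NA,  NA,  NA,
    "PUL1", "boiled soybeans",    g[3], 14.8, 9.8, 1.4, 8.4, 6.6, 65.0, 0.0, 0.0, 0.0, 1.8, 0.0, 0.0,
    "PUL2", "sweet bean paste",   g[3], 5.6, 0.6, 0.1, 54.0, 4.8, 39.0,  NA,  NA,  NA,  NA,  NA,  NA,
    "PUL3", "roasted peanuts",    g[3], 25.0, 49.0, 8.3, 19.6, 7.3, 2.0, 0.0, 0.0, 0.0, 4.5, 0.0, 0.0,
    "FRU1", "apple",              g[4], 0.2, 0.3, 0.0, 14.6, 1.9, 84.0, 1.4, 6.3, 0.0, 4.8, 0.0, 0.0,
    "FRU2", "banana",             g[4], 1.1, 0.2, 0.1, 22.5, 1.1, 75.0, 2.6, 2.4, 0.0, 10.5, 0.0, 0.0,
    "FRU3", "dried apple",        g[4], 1.0, 0.4, 0.0, 64.0, 9.0, 15.0,  NA,  NA,  NA,  NA,  NA,  NA,
    "FRU4", "carrot",             g[4], 0.7, 0.2, 0.0,  9.3, 2.8, 89.0, 1.7, 1.6, 0.0, 3.0, 0.0, 0.0,
    "FRU5", "imported fruit",     g[4], 0.8, 0.3, 0.1, 13.0, 1.7, 84.0,  NA,  NA,  NA,  NA,  NA,  NA,
    "FRU6", "mystery vegetable",  g[4], 1.5, 0.2, 0.0,  5.0, 2.0, 90.0,  NA,  NA,  NA,  NA,  NA,  NA,
    "PRO1", "whole milk",         g[5], 3.3, 3.8, 2.3,  4.8, 0.0, 87.0, 0.0, 0.0, 0.0, 0.0, 4.8, 0.0,
    "PRO2", "sweetened yogurt",   g[5], 4.3, 0.2, 0.1, 11.9, 0.0, 82.0, 0.4, 0.4, 0.0, 6.0, 4.2, 0.0,
    "PRO3", "chicken",            g[5], 22.0, 6.0, 1.6,  0.0, 0.0, 72.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0,
    "PRO4", "fish paste cake",    g[5], 12.0, 0.9, 0.3, 13.9, 0.0, 70.0,  NA,  NA,  NA,  NA,  NA,  NA,
    "PRO5", "hen egg",            g[5], 12.3, 10.3, 3.1, 0.3, 0.0, 75.0, 0.3, 0.0, 0.0, 0.0, 0.0, 0.0,
    "PRO6", "processed cheese",   g[5], 22.7, 26.0, 16.0, 1.3, 0.0, 45.0,  NA,  NA,  NA,  NA,  NA,  NA,
    "CON1", "milk chocolate",     g[6], 6.9, 34.0, 20.0, 55.8, 3.9, 1.0, 0.3, 0.3, 0.0, 49.0, 2.0, 0.2,
    "CON2", "butter cookie",      g[6], 5.7, 27.0, 12.0, 62.0, 1.4, 3.0, 0.8, 0.7, 0.0, 24.0, 0.5, 2.0,
    "CON3", "hard candy",         g[6], 0.0, 0.0, 0.0, 97.5, 0.0, 2.0,  NA,  NA,  NA,  NA,  NA,  NA,
    "CON4", "sweet rice cake",    g[6], 4.6, 0.5, 0.2, 50.3, 1.5, 43.0,  NA,  NA,  NA,  NA,  NA,  NA,
    "CON5", "imported biscuit",   g[6], 7.0, 20.0, 9.0, 67.0, 2.0, 2.5,  NA,  NA,  NA,  NA,  NA,  NA,
    "JUI1", "orange juice 100%",  g[7], 0.7, 0.1, 0.0, 10.6, 0.2, 88.0, 2.1, 2.6, 0.0, 4.9, 0.0, 0.0,
    "JUI2", "apple juice 100%",   g[7], 0.1, 0.1, 0.0, 11.4, 0.0, 88.0, 2.4, 6.0, 0.0, 2.0, 0.0, 0.0,
    "JUI3", "vegetable juice",    g[7], 0.9, 0.1, 0.0,  6.7, 0.7, 91.0, 1.5, 1.5, 0.0, 1.0, 0.0, 0.0,
    "SSB1", "cola",               g[8], 0.0, 0.0, 0.0, 11.4, 0.0, 88.5,  NA,  NA,  NA,  NA,  NA,  NA,
    "SSB2", "sweet milk coffee",  g[8], 2.2, 2.0, 1.3,  8.2, 0.0, 86.0, 0.0, 0.0, 0.0, 4.4, 3.4, 0.0,
    "SSB3", "sports drink",       g[8], 0.0, 0.0, 0.0,  5.1, 0.0, 94.7, 1.8, 1.6, 0.0, 1.5, 0.0, 0.0,
    "SSB4", "fruit drink 30%",    g[8], 0.2, 0.0, 0.0, 10.8, 0.1, 88.0, 2.2, 2.6, 0.0, 5.2, 0.0, 0.0,
    "SEA1", "soy sauce",          g[9], 7.7, 0.0, 0.0, 10.1, 0.0, 67.0, 0.8, 0.2, 0.1, 0.1, 0.0, 0.1,
    "SEA2", "mirin",              g[9], 0.3, 0.0, 0.0, 43.2, 0.0, 47.0,  NA,  NA,  NA,  NA,  NA,  NA,
    "SEA3", "tomato ketchup",     g[9], 1.6, 0.2, 0.0, 27.6, 1.7, 66.0,  NA,  NA,  NA,  NA,  NA,  NA,
    "SEA4", "miso",               g[9], 12.5, 6.0, 1.0, 21.9, 4.9, 45.0, 1.1, 0.3, 0.0, 0.2, 0.0, 0.4,
    "SEA5", "sweet sauce",        g[9], 1.2, 0.1, 0.0, 30.0, 1.0, 60.0,  NA,  NA,  NA,  NA,  NA,  NA,
    "SEA6", "table salt",         g[9], 0.0, 0.0, 0.0,  0.0, 0.0, 0.1, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0,
    "OTH1", "mixed lunch dish",   g[10], 6.0, 5.0, 1.5, 18.0, 1.2, 68.0,  NA,  NA,  NA,  NA,  NA,  NA,
    "OTH2", "green tea",          g[10], 0.2, 0.0, 0.0,  0.2, 0.0, 99.5, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0,
    "OTH3", "jelly snack",        g[10], 0.1, 0.1, 0.0, 16.0, 0.5, 83.0,  NA,  NA,  NA,  NA,  NA,  NA,
    "OTH4", "unknown food",       g[10], 2.0, 2.0, 0.5,  8.0, 1.0, 85.0,  NA,  NA,  NA,  NA,  NA,  NA
  )

  opt <- function(codes, values) {
    out <- rep(if (is.character(values)) NA_character_ else NA_real_, nrow(base))
    out[match(codes, base$food_code)] <- values
    out
  }
  flag <- function(codes) base$food_code %in% codes

  base$carbohydrate_is_all_sugar <- flag(c("SUG1", "SUG3", "CON3", "SSB1", "SEA2", "PRO4"))
  base$no_added_sugar <- flag(c("CER1", "CER3", "CER4", "CER5", "CER6",
                                "SUG3", "SUG4", "PUL1", "PUL3",
                                "FRU1", "FRU2", "FRU3", "FRU4", "FRU5",
                                "PRO1", "PRO3", "PRO5",
                                "JUI1", "JUI2", "JUI3", "SEA4", "OTH2"))
  base$all_sugar_added <- flag(c("SUG1", "CON3", "SSB1", "SEA2"))
  base$is_fruit_juice_or_honey_or_syrup <- flag(c("SUG3", "SUG4",
                                                  "JUI1", "JUI2", "JUI3", "SSB4"))
  base$processed <- flag(c("PUL2", "PRO4", "CON4", "SEA1", "OTH3"))
  base$literature_total_sugar <- opt(c("SUG4", "PUL2", "CON4", "SEA3"),
                                     c(60, 35, 40, 22.3))
  base$label_added_sugar <- opt(c("CER2", "CON1", "SSB3", "SEA3"),
                                c(1.2, 49.5, 4.9, 16.9))
  base$label_free_sugar <- opt(c("CER2", "CON1", "SSB3", "SEA3"),
                               c(1.2, 49.5, 4.9, 16.9))
  base$ref_raw_form <- opt(c("CER4", "FRU3"), c("CER3", "FRU1"))
  base$ref_similar <- opt(c("CER6", "PRO6", "SEA5", "OTH1"),
                          c("CER1", "PRO1", "SEA3", "CER1"))
  base$ref_unsweetened <- opt(c("SSB2", "SSB4"), c("PRO1", "JUI1"))
  base$recipe <- opt(c("SUG2", "CON2", "OTH1"),
                     c("SUG1:0.45;FRU1:0.55", "SUG1:0.25;CER2:0.55",
                       "CER1:0.6;PRO3:0.3;SEA1:0.1"))
  for (nm in paste0("foreign_", saccharide_names())) base[[nm]] <- NA_real_
  base[base$food_code == "FRU5", paste0("foreign_", saccharide_names())] <-
    as.list(c(2, 3, 0, 4, 0, 1))
  base[base$food_code == "CON5", paste0("foreign_", saccharide_names())] <-
    as.list(c(1, 1, 0, 20, 1, 2))
  base$foreign_mono_eq <- flag(c("FRU5", "CON5"))
  base$foreign_added_sugar <- opt("CON5", 21)
  base$foreign_free_sugar <- opt("CON5", 21)

  # ground truth follows from the construction above (hand arithmetic)
  truth <- tibble::tribble(
    ~food_code, ~true_total, ~true_added, ~true_free, ~true_total_step, ~true_free_step,
    "CER1", 0.3, 0, 0, 1L, 1L,
    "CER2", 4.0, 1.2, 1.2, 1L, 4L,
    "CER3", 0.7, 0, 0, 1L, 1L,
    "CER4", 0.7 * (100 - 83) / (100 - 15), 0, 0, 4L, 1L,
    "CER5", 0.7, 0, 0, 1L, 1L,
    "CER6", 0.3, 0, 0, 5L, 1L,
    "SUG1", 99.9, 99.9, 99.9, 2L, 3L,
    "SUG2", 47.0, 0.45 * 99.9, 0.45 * 99.9, 1L, 5L,
    "SUG3", 81.9, 0, 81.9, 2L, 2L,
    "SUG4", 60.0, 0, 60.0, 3L, 2L,
    "PUL1", 1.8, 0, 0, 1L, 1L,
    "PUL2", 35.0, 17.5, 17.5, 3L, 9L,
    "PUL3", 4.5, 0, 0, 1L, 1L,
    "FRU1", 12.5, 0, 0, 1L, 1L,
    "FRU2", 15.5, 0, 0, 1L, 1L,
    "FRU3", 55.0, 0, 0, 4L, 1L,   # dry-weight value capped at available carbohydrate
    "FRU4", 6.3, 0, 0, 1L, 1L,
    "FRU5", 5 + 0.95 * 5, 0, 0, 6L, 1L,
    "FRU6", 0, 0, 0, 7L, 11L,
    "PRO1", 4.8, 0, 0, 1L, 1L,
    "PRO2", 11.0, 6.8, 6.8, 1L, 8L,
    "PRO3", 0, 0, 0, 1L, 1L,
    "PRO4", 13.9, 6.95, 6.95, 2L, 9L,
    "PRO5", 0.3, 0, 0, 1L, 1L,
    "PRO6", 1.3, 0, 0, 5L, 6L,    # similar-item value capped at available carbohydrate
    "CON1", 51.8, 49.5, 49.5, 1L, 4L,
    "CON2", 28.0, 0.25 * 99.9 + 0.55 * 1.2, 0.25 * 99.9 + 0.55 * 1.2, 1L, 5L,
    "CON3", 97.5, 97.5, 97.5, 2L, 3L,
    "CON4", 40.0, 20.0, 20.0, 3L, 9L,
    "CON5", 2 + 0.95 * 23, 21, 21, 6L, 10L,
    "JUI1", 9.6, 0, 9.6, 1L, 2L,
    "JUI2", 10.4, 0, 10.4, 1L, 2L,
    "JUI3", 4.0, 0, 4.0, 1L, 2L,
    "SSB1", 11.4, 11.4, 11.4, 2L, 3L,
    "SSB2", 7.8, 3.0, 3.0, 1L, 7L,
    "SSB3", 4.9, 4.9, 4.9, 1L, 4L,
    "SSB4", 10.0, 0.4, 10.0, 1L, 7L,
    "SEA1", 1.3, 0.65, 0.65, 1L, 9L,
    "SEA2", 43.2, 43.2, 43.2, 2L, 3L,
    "SEA3", 22.3, 16.9, 16.9, 3L, 4L,
    "SEA4", 2.0, 0, 0, 1L, 1L,
    "SEA5", 22.3, 22.3 * (16.9 / 22.3), 22.3 * (16.9 / 22.3), 5L, 6L,
    "SEA6", 0, 0, 0, 1L, 11L,
    "OTH1", 0.3, 0.6 * 0 + 0.3 * 0 + 0.1 * 0.65, 0.6 * 0 + 0.3 * 0 + 0.1 * 0.65, 5L, 5L,
    "OTH2", 0, 0, 0, 1L, 1L,
    "OTH3", 0, 0, 0, 7L, 9L,
    "OTH4", 0, 0, 0, 7L, 11L
  )

  # random filler foods in the staple groups: full saccharide data, no
  # added sugar (step 1 / step 1 by construction)
  n_x <- config$n_extra_per_group
  if (n_x > 0) {
    staple_groups <- g[c(1, 3, 4, 5, 10)]
    extras <- lapply(seq_along(staple_groups), function(k) {
      grp <- staple_groups[k]
      tibble::tibble(
        food_code = sprintf("XTR%d_%d", k, seq_len(n_x)),
        name = sprintf("filler food %s %d", grp, seq_len(n_x)),
        food_group = grp,
        protein = stats::runif(n_x, 1, 15),
        fat = stats::runif(n_x, 0.1, 10),
        saturated_fat = stats::runif(n_x, 0, 2),
        carbohydrate = stats::runif(n_x, 5, 25),
        dietary_fiber = stats::runif(n_x, 0, 3),
        water = stats::runif(n_x, 55, 85),
        glucose = stats::runif(n_x, 0, 0.6),
        fructose = stats::runif(n_x, 0, 0.6),
        galactose = 0,
        sucrose = stats::runif(n_x, 0, 0.8),
        lactose = 0,
        maltose = stats::runif(n_x, 0, 0.3),
        no_added_sugar = TRUE
      )
    })
    extras <- dplyr::bind_rows(extras)
    truth_x <- tibble::tibble(
      food_code = extras$food_code,
      true_total = extras$glucose + extras$fructose + extras$galactose +
        extras$sucrose + extras$lactose + extras$maltose,
      true_added = 0, true_free = 0,
      true_total_step = 1L, true_free_step = 1L)
    base <- dplyr::bind_rows(base, extras)
    truth <- dplyr::bind_rows(truth, truth_x)
  }
  base$energy <- 4 * base$protein + 9 * base$fat + 4 * base$carbohydrate
  for (fl in c("carbohydrate_is_all_sugar", "no_added_sugar", "all_sugar_added",
               "is_fruit_juice_or_honey_or_syrup", "processed",
               "foreign_mono_eq")) {
    base[[fl]][is.na(base[[fl]])] <- FALSE
  }
  list(food_table = base, truth = truth)
}

#' Food-level nutrient table for the intake pipeline
#'
#' Joins a food composition table with its sugar assignments into the
#' per-100 g nutrient table consumed by [daily_intake()].
#'
#' @param food_table Food composition table.
#' @param sugar_db Output of [build_sugar_db()] for the same table.
#' @return Tibble: one row per food with nutrient and sugar contents.
#' @export
nutrient_table <- function(food_table, sugar_db) {
  dplyr::inner_join(
    dplyr::select(food_table, "food_code", "food_group", "energy", "protein",
                  "fat", "saturated_fat", "carbohydrate"),
    dplyr::select(sugar_db, "food_code", "total_sugar", "added_sugar",
                  "free_sugar"),
    by = "food_code")
}

#' Generate a synthetic cohort with covariates and latent outcomes
#'
#' Draws child, parental and household covariates independently from the
#' configured marginals (sex and age as exact counts at the default cohort
#' size), constructs raw questionnaire-style fields consistent with each
#' drawn category, computes the latent excessive-intake probability from
#' the configured logistic model (intercept calibrated to the configured
#' prevalence), and assigns per-child targets for daily energy and free
#' sugar percent of energy, the latter drawn from the calibrated gamma
#' distribution truncated above or below the threshold according to the
#' latent outcome.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @return List: `raw` (raw cohort table for [derive_covariates()]) and
#'   `truth` (tibble with the generated categories, linear predictor,
#'   latent probability, `excessive`, `target_energy`, `target_pct`;
#'   attribute `intercept` carries the calibrated intercept).
#' @export
gen_cohort <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_children
  id <- sprintf("C%04d", seq_len(n))
  sex <- sample_categories(n, config$sex_counts)
  age <- as.integer(sample_categories(n, config$age_counts))

  cat_draw <- function(v) {
    p <- config$marginals[[v]]
    sample(names(p), n, replace = TRUE, prob = p)
  }
  cats <- tibble::tibble(
    child_id = id, sex = sex, age = as.character(age),
    weight_status = cat_draw("weight_status"),
    sleep = cat_draw("sleep"),
    outdoor = cat_draw("outdoor"),
    screen = cat_draw("screen"),
    maternal_age = cat_draw("maternal_age"),
    maternal_weight_status = cat_draw("maternal_weight_status"),
    maternal_education = cat_draw("maternal_education"),
    maternal_occupation = cat_draw("maternal_occupation"),
    maternal_smoking = cat_draw("maternal_smoking"),
    paternal_age = cat_draw("paternal_age"),
    paternal_weight_status = cat_draw("paternal_weight_status"),
    paternal_education = cat_draw("paternal_education"),
    paternal_occupation = cat_draw("paternal_occupation"),
    paternal_smoking = cat_draw("paternal_smoking"),
    grandparents = cat_draw("grandparents"),
    siblings = cat_draw("siblings"),
    income = cat_draw("income")
  )

  cutoffs <- readr::read_csv(synthetic_child_bmi_cutoffs(), show_col_types = FALSE)
  m <- match(paste(age, sex), paste(cutoffs$age_years, cutoffs$sex))
  lower <- cutoffs$bmi_lower[m]; upper <- cutoffs$bmi_upper[m]
  child_bmi <- ifelse(
    cats$weight_status == "Underweight", lower - stats::runif(n, 0.3, 1.5),
    ifelse(cats$weight_status == "Overweight and obese",
           upper + stats::runif(n, 0.1, 3),
           stats::runif(n, lower + 0.1, upper - 0.1)))
  height <- pmax(stats::rnorm(n, 93 + 6.5 * (age - 3), 3.5), 80)
  weight <- child_bmi * (height / 100)^2

  sleep_total <- ifelse(cats$sleep == "<10", stats::runif(n, 8.6, 9.9),
                        stats::runif(n, 10.05, 11.8))
  nap <- stats::runif(n, 0.8, 1.6)

  # weekday/weekend pairs whose 5/7-2/7 weighting equals a drawn target
  split_weekly <- function(target, jitter) {
    d <- stats::runif(n, -jitter, jitter)
    data.frame(weekday = pmax(target - d * 2 / 5, 0),
               weekend = pmax(target + d, 0))
  }
  outdoor_target <- dplyr::case_when(
    cats$outdoor == "<1" ~ stats::runif(n, 0.15, 0.95),
    cats$outdoor == ">=1 to <2" ~ stats::runif(n, 1.05, 1.95),
    TRUE ~ stats::runif(n, 2.05, 3.5))
  outdoor_we <- split_weekly(outdoor_target, 0.1)
  screen_target <- dplyr::case_when(
    cats$screen == "<0.5" ~ stats::runif(n, 0.05, 0.45),
    cats$screen == ">=0.5 to <1" ~ stats::runif(n, 0.53, 0.97),
    TRUE ~ stats::runif(n, 1.05, 3.0))
  screen_we <- split_weekly(screen_target, 0.03)

  adult_fields <- function(prefix) {
    a <- cats[[paste0(prefix, "_age")]]
    w <- cats[[paste0(prefix, "_weight_status")]]
    e <- cats[[paste0(prefix, "_education")]]
    age_y <- dplyr::case_when(a == "20 to 29" ~ stats::runif(n, 23, 29.5),
                              a == "30 to 39" ~ stats::runif(n, 30.2, 39.5),
                              TRUE ~ stats::runif(n, 40.2, 48))
    bmi <- dplyr::case_when(w == "Underweight" ~ stats::runif(n, 16.5, 18.2),
                            w == "Normal" ~ stats::runif(n, 18.8, 24.5),
                            TRUE ~ stats::runif(n, 25.3, 31))
    ht <- if (prefix == "maternal") stats::rnorm(n, 158, 5) else stats::rnorm(n, 171, 5.5)
    edu <- dplyr::case_when(e == "<=12" ~ stats::runif(n, 9, 12.5),
                            e == "13 to 14" ~ stats::runif(n, 13.1, 14.6),
                            TRUE ~ stats::runif(n, 15.1, 18))
    list(age = age_y, height = ht, weight = bmi * (ht / 100)^2, edu = edu)
  }
  mo <- adult_fields("maternal")
  fa <- adult_fields("paternal")

  n_sib <- ifelse(cats$siblings == "0", 0L,
                  ifelse(cats$siblings == "1", 1L,
                         sample(2:3, n, replace = TRUE)))
  gp <- cats$grandparents == "Yes"
  hh_size <- 3L + n_sib + ifelse(gp, sample(1:2, n, replace = TRUE), 0L)
  equiv <- dplyr::case_when(
    cats$income == "Low" ~ stats::runif(n, 1.2e6, 2.35e6),
    cats$income == "Middle" ~ stats::runif(n, 2.40e6, 3.32e6),
    TRUE ~ stats::runif(n, 3.36e6, 6e6))
  income_raw <- equiv * sqrt(hh_size)

  raw <- tibble::tibble(
    child_id = id, sex = sex, age_years = age,
    height_cm = height, weight_kg = weight,
    nap_h = nap, night_sleep_h = sleep_total - nap,
    outdoor_weekday_h = outdoor_we$weekday, outdoor_weekend_h = outdoor_we$weekend,
    screen_weekday_h = screen_we$weekday, screen_weekend_h = screen_we$weekend,
    maternal_age_years = mo$age, maternal_height_cm = mo$height,
    maternal_weight_kg = mo$weight, maternal_education_years = mo$edu,
    maternal_occupation = cats$maternal_occupation,
    maternal_smoking = cats$maternal_smoking == "Yes",
    paternal_age_years = fa$age, paternal_height_cm = fa$height,
    paternal_weight_kg = fa$weight, paternal_education_years = fa$edu,
    paternal_occupation = cats$paternal_occupation,
    paternal_smoking = cats$paternal_smoking == "Yes",
    lives_with_grandparents = gp,
    n_siblings = n_sib,
    household_income_yen = income_raw,
    household_size = hh_size
  )

  # latent outcome from the configured logistic model
  eta <- rep(0, n)
  for (v in names(config$log_or)) {
    eta <- eta + unname(config$log_or[[v]][cats[[v]]])
  }
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta)) -
                         config$prevalence_target,
                       interval = c(-25, 15), tol = 1e-10)$root
  p_exc <- stats::plogis(b0 + eta)
  excessive <- stats::runif(n) < p_exc

  target_energy <- rtrunc_norm(n, config$energy_mean, config$energy_sd,
                               config$energy_range[1], config$energy_range[2])
  sh <- config$gamma_shape; ra <- config$gamma_rate
  target_pct <- numeric(n)
  u <- stats::runif(n)
  lo_p <- stats::pgamma(config$pct_range[1], sh, ra)
  th_p <- stats::pgamma(config$threshold, sh, ra)
  hi_p <- stats::pgamma(config$pct_range[2], sh, ra)
  target_pct[excessive] <- stats::qgamma(th_p + u[excessive] * (hi_p - th_p), sh, ra)
  target_pct[!excessive] <- stats::qgamma(lo_p + u[!excessive] * (th_p - lo_p), sh, ra)

  truth <- dplyr::mutate(cats, eta = eta, p_excessive = p_exc,
                         excessive = excessive,
                         target_energy = target_energy,
                         target_pct = target_pct)
  attr(truth, "intercept") <- b0
  list(raw = raw, truth = truth)
}

#' Generate 3-day weighed dietary records hitting per-child targets
#'
#' For each child and recorded day (two weekdays with a nursery-school
#' lunch, one weekend day) a basket of staple foods and sugar-dense foods
#' (confectionaries, sugar-sweetened beverages, sugars and jams, juices;
#' confectionaries sampled most often) is drawn, and the gram amounts of
#' the two sub-baskets are rescaled by an exact linear solve so that the
#' day's computed energy equals the child's energy target and the free
#' sugar percent of energy equals the child's percent-energy target
#' (amount rescaling is cheap and exact, unlike rejection sampling).
#'
#' @param cohort Output of [gen_cohort()].
#' @param nutrients Output of [nutrient_table()] for the generated food db.
#' @param config A [sim_config()].
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @return Tibble of record entries: `child_id`, `day_index`, `day_type`,
#'   `food_code`, `amount` (g).
#' @export
gen_dietary_records <- function(cohort, nutrients, config = sim_config(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sugary_groups <- names(config$sugary_group_weights)
  sugary <- nutrients[nutrients$food_group %in% sugary_groups &
                        nutrients$free_sugar > 0, ]
  staple <- nutrients[!nutrients$food_group %in% sugary_groups &
                        nutrients$free_sugar <= 3, ]
  if (!nrow(sugary)) {
    stop("unreachable targets: food db has no sugar-bearing foods in the ",
         "sugar-dense groups", call. = FALSE)
  }
  base_amount <- c("Cereals and potatoes" = 150, "Pulses and nuts" = 40,
                   "Fruits and vegetables" = 100, "Protein rich animal foods" = 120,
                   "Seasonings" = 15, "Other foods" = 100,
                   "Confectionaries" = 35, "Sugar-sweetened beverages" = 160,
                   "Sugars and jams" = 10, "Fruit and vegetable juices" = 120)
  truth <- cohort$truth
  n <- nrow(truth)
  out <- vector("list", n * 3L)
  k <- 0L
  for (i in seq_len(n)) {
    e_target <- truth$target_energy[i]
    p_target <- truth$target_pct[i]
    f_target <- p_target / 100 * e_target / 4  # grams of free sugar per day
    for (d in 1:3) {
      for (attempt in 1:25) {
        st <- staple[sample.int(nrow(staple), min(config$staples_per_day,
                                                  nrow(staple))), ]
        grp <- sample(sugary_groups, config$sugary_per_day, replace = TRUE,
                      prob = config$sugary_group_weights)
        su <- dplyr::bind_rows(lapply(grp, function(gg) {
          cand <- sugary[sugary$food_group == gg, ]
          cand[sample.int(nrow(cand), 1L), ]
        }))
        su <- su[!duplicated(su$food_code), ]
        amt_st <- base_amount[st$food_group] * stats::runif(nrow(st), 0.7, 1.3)
        amt_su <- base_amount[su$food_group] * stats::runif(nrow(su), 0.7, 1.3)
        e1 <- sum(amt_su / 100 * su$energy); f1 <- sum(amt_su / 100 * su$free_sugar)
        e2 <- sum(amt_st / 100 * st$energy); f2 <- sum(amt_st / 100 * st$free_sugar)
        det <- e1 * f2 - e2 * f1
        a <- (e_target * f2 - e2 * f_target) / det
        b <- (e1 * f_target - e_target * f1) / det
        if (is.finite(a) && is.finite(b) && a > 0 && b > 0) break
        if (attempt == 25) {
          stop("could not construct a dietary day matching the targets ",
               "(free sugar shares of the sampled baskets bracket no solution)",
               call. = FALSE)
        }
      }
      k <- k + 1L
      out[[k]] <- tibble::tibble(
        child_id = truth$child_id[i],
        day_index = d,
        day_type = if (d < 3) "weekday_school_lunch" else "weekend",
        food_code = c(su$food_code, st$food_code),
        amount = unname(c(a * amt_su, b * amt_st)))
    }
  }
  dplyr::bind_rows(out)
}

#' Simulate a complete synthetic study
#'
#' Food composition table (with hidden ground truth), sugar database built
#' from it, cohort, and dietary records, all from one seed.
#'
#' @param seed Integer seed controlling every random draw.
#' @param config A [sim_config()].
#' @return List: `food_table`, `food_truth`, `sugar_db`, `nutrients`,
#'   `cohort_raw`, `cohort_truth`, `records`, `config`, `seed`.
#' @export
simulate_study <- function(seed, config = sim_config()) {
  set.seed(seed)
  food <- gen_food_db(config, seed = NULL)
  db <- build_sugar_db(food$food_table)
  nut <- nutrient_table(food$food_table, db)
  cohort <- gen_cohort(config, seed = NULL)
  records <- gen_dietary_records(cohort, nut, config, seed = NULL)
  list(food_table = food$food_table, food_truth = food$truth,
       sugar_db = db, nutrients = nut,
       cohort_raw = cohort$raw, cohort_truth = cohort$truth,
       records = records, config = config, seed = seed)
}

#' Run the full study pipeline on synthetic data
#'
#' Chains simulate, database build, intake estimation, covariate
#' derivation and association analysis, optionally writing every table as
#' CSV together with a provenance file (seed, configuration hash, package
#' version).
#'
#' @param seed Integer seed.
#' @param config A [sim_config()].
#' @param outdir Optional output directory (created if needed).
#' @param welch,continuity_correction Analysis flags passed through.
#' @return List: the simulation (`sim`), `intake` summaries,
#'   `intake_table`, `association`, `prevalence`, and `provenance`.
#' @export
run_study_pipeline <- function(seed, config = sim_config(), outdir = NULL,
                               welch = FALSE, continuity_correction = FALSE) {
  sim <- simulate_study(seed, config)
  intake <- compute_intake(sim$records, sim$nutrients,
                           threshold = config$threshold)
  t3 <- cohort_intake_table(intake, welch = welch)
  covs <- derive_covariates(sim$cohort_raw)
  outcome <- intake$excessive[match(covs$child_id, intake$child_id)]
  t4 <- association_table(covs, outcome,
                          continuity_correction = continuity_correction)
  prov <- list(seed = seed, config_hash = rlang::hash(config),
               package_version = as.character(utils::packageVersion("freesugar")))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(sim$food_table, file.path(outdir, "food_table.csv"))
    readr::write_csv(sim$sugar_db, file.path(outdir, "sugar_db.csv"))
    readr::write_csv(sim$cohort_raw, file.path(outdir, "cohort_raw.csv"))
    readr::write_csv(sim$records, file.path(outdir, "dietary_records.csv"))
    readr::write_csv(intake, file.path(outdir, "intake_summaries.csv"))
    readr::write_csv(t3$nutrients, file.path(outdir, "intake_table_nutrients.csv"))
    readr::write_csv(t3$group_share, file.path(outdir, "intake_table_group_share.csv"))
    readr::write_csv(format_association_table(t4),
                     file.path(outdir, "association_table.csv"))
    writeLines(sprintf("%s: %s", names(prov), unlist(prov)),
               file.path(outdir, "provenance.txt"))
  }
  list(sim = sim, intake = intake, intake_table = t3, association = t4,
       prevalence = prevalence_excessive(intake), provenance = prov)
}
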