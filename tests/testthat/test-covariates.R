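test_that("week-weighted hours combine weekday and weekend as 5/7 and 2/7", {
  expect_equal(weekly_weighted_hours(1, 1), 1)
  expect_equal(weekly_weighted_hours(0.7, 1.4), 0.9)
  expect_equal(weekly_weighted_hours(0, 3.5), 1)
  expect_error(weekly_weighted_hours(-1, 0), "non-negative")
})

test_that("total sleep is nap plus night sleep", {
  expect_equal(total_sleep(1.5, 9), 10.5)
  expect_equal(total_sleep(0, 9.5), 9.5)
  expect_error(total_sleep(-0.1, 8), "non-negative")
})

test_that("categorisation is left-closed at every printed cutpoint", {
  screen <- c("<0.5", ">=0.5 to <1", ">=1")
  expect_equal(as.character(categorize(0.5, c(0.5, 1), screen)), ">=0.5 to <1")
  expect_equal(as.character(categorize(1, c(0.5, 1), screen)), ">=1")
  expect_equal(as.character(categorize(10, 10, c("<10", ">=10"))), ">=10")
  outdoor <- c("<1", ">=1 to <2", ">=2")
  expect_equal(as.character(categorize(1.99, c(1, 2), outdoor)), ">=1 to <2")
  # monotone: larger values never map to a lower-ordered category
  x <- sort(runif(100, 0, 3))
  k <- as.integer(categorize(x, c(1, 2), outdoor))
  expect_true(!is.unsorted(k))
})

test_that("adult weight status uses the 18.5 / 25 boundaries inclusively upward", {
  expect_equal(as.character(adult_weight_status(18.5)), "Normal")
  expect_equal(as.character(adult_weight_status(17)), "Underweight")
  expect_equal(as.character(adult_weight_status(25)), "Overweight and obese")
  expect_error(adult_weight_status(0), "positive")
})

test_that("child weight status looks up age/sex cutoffs and matches the adult rule", {
  tab <- readr::read_csv(synthetic_child_bmi_cutoffs(), show_col_types = FALSE)
  lo <- tab$bmi_lower[tab$age_years == 4 & tab$sex == "Girls"]
  hi <- tab$bmi_upper[tab$age_years == 4 & tab$sex == "Girls"]
  expect_equal(as.character(child_weight_status(lo - 0.5, 4, "Girls", tab)),
               "Underweight")
  expect_equal(as.character(child_weight_status(hi, 4, "Girls", tab)),
               "Overweight and obese")  # upper boundary inclusive
  expect_equal(as.character(child_weight_status(lo, 4, "Girls", tab)), "Normal")
  expect_error(child_weight_status(16, 9, "Girls", tab), "age/sex")

  # with adult thresholds in the table, the child rule reduces to the adult one
  adult_tab <- adult_equivalent_cutoffs()
  bmis <- c(17, 18.5, 20, 25, 27)
  expect_equal(as.character(child_weight_status(bmis, rep(5, 5), rep("Boys", 5),
                                                adult_tab)),
               as.character(adult_weight_status(bmis)))
})

test_that("income tertiles bucket the equivalised income at the printed cutpoints", {
  # household size 1: scale divisor 1
  expect_equal(as.character(equivalized_income_tertile(2380000, 1)), "Middle")
  expect_equal(as.character(equivalized_income_tertile(3340000, 1)), "High")
  expect_equal(as.character(equivalized_income_tertile(1e6, 1)), "Low")
  # square-root equivalence scale
  expect_equal(as.character(equivalized_income_tertile(2380000 * 2, 4)), "Middle")
  expect_error(equivalized_income_tertile(1e6, 0), "household_size")
})

test_that("derived covariates reproduce the generator's category ground truth", {
  cfg <- sim_config(n_children = 120)
  cohort <- gen_cohort(cfg, seed = 21)
  covs <- derive_covariates(cohort$raw)
  expect_equal(nrow(covs), 120)
  for (v in setdiff(names(covs), "child_id")) {
    expect_equal(as.character(covs[[v]]), cohort$truth[[v]],
                 info = paste("covariate:", v))
  }
  # reference levels as used in the association analysis
  expect_equal(levels(covs$weight_status)[1], "Normal")
  expect_equal(levels(covs$sex)[1], "Boys")
  expect_equal(levels(covs$maternal_occupation)[1], "Professional and manager")
})
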