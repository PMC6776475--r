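entries1 <- function() {
  tibble::tibble(child_id = "c1", day_index = 1L, food_code = "N1", amount = 150)
}

test_that("daily intake scales per-100 g contents and is additive", {
  nut <- tiny_nutrient_table()
  d <- daily_intake(entries1(), nut)
  expect_equal(d$free_sugar, 45)   # 150 g of 30 g/100 g
  expect_equal(d$energy, 600)
  expect_equal(d$`fs_Confectionaries`, 45)

  two <- tibble::tibble(child_id = "c1", day_index = 1L,
                        food_code = c("N1", "N1"), amount = c(50, 50))
  one <- tibble::tibble(child_id = "c1", day_index = 1L,
                        food_code = "N1", amount = 100)
  expect_equal(daily_intake(two, nut), daily_intake(one, nut))

  bad <- tibble::tibble(child_id = "c1", day_index = 1L,
                        food_code = "UNKNOWN", amount = 10)
  expect_error(daily_intake(bad, nut), "UNKNOWN")
})

test_that("mean daily intake averages days and ignores day order", {
  nut <- tiny_nutrient_table()
  e <- tibble::tibble(child_id = "c1", day_index = rep(1:3, each = 1),
                      food_code = "N1", amount = c(200/3, 100, 400/3))
  # free sugar per day: 20, 30, 40 -> mean 30
  m <- mean_daily_intake(daily_intake(e, nut))
  expect_equal(m$free_sugar, 30)
  e2 <- e; e2$day_index <- c(3L, 1L, 2L)
  expect_equal(mean_daily_intake(daily_intake(e2, nut))$free_sugar, 30)
  # identical days: the mean is that day's value
  e3 <- tibble::tibble(child_id = "c1", day_index = 1:3,
                       food_code = "N1", amount = 100)
  expect_equal(mean_daily_intake(daily_intake(e3, nut))$free_sugar, 30)
  expect_error(mean_daily_intake(daily_intake(e, nut)[0, ]), "no recorded days")
})

test_that("day weights reweight the mean", {
  nut <- tiny_nutrient_table()
  e <- tibble::tibble(child_id = "c1", day_index = 1:3,
                      food_code = "N1", amount = c(200/3, 100, 400/3))
  m <- mean_daily_intake(daily_intake(e, nut), day_weights = c(5, 5, 4))
  expect_equal(m$free_sugar, (5 * 20 + 5 * 30 + 4 * 40) / 14)
})

test_that("percent of energy uses the configured conversion factors", {
  expect_equal(percent_energy(50, 2000), 10)
  expect_equal(percent_energy(0, 1500), 0)
  expect_equal(percent_energy(26.8, 1371), 26.8 * 4 / 1371 * 100)
  expect_equal(percent_energy(10, 900, kcal_per_gram = 9), 10)
  expect_error(percent_energy(10, 0), "positive")
})

test_that("excessive-intake classification has a closed lower bound at 10%", {
  expect_true(classify_excessive(12.4))
  expect_false(classify_excessive(6.5))
  expect_true(classify_excessive(10))
  # monotone non-decreasing
  x <- sort(runif(50, 0, 20))
  expect_true(!is.unsorted(as.integer(classify_excessive(x))))
})

test_that("prevalence is the percentage of excessive children", {
  s <- data.frame(excessive = rep(c(TRUE, FALSE), c(72, 260)))
  expect_equal(round(prevalence_excessive(s), 1), 21.7)
  expect_equal(prevalence_excessive(data.frame(excessive = rep(FALSE, 5))), 0)
  expect_equal(prevalence_excessive(data.frame(excessive = rep(TRUE, 5))), 100)
  expect_error(prevalence_excessive(data.frame(excessive = logical(0))), "empty")
})

test_that("group-wise free sugar adds up and intake scales linearly", {
  cfg <- sim_config(n_children = 40)
  sim <- simulate_study(5, cfg)
  intake <- compute_intake(sim$records, sim$nutrients)
  grp_sum <- rowSums(intake[, paste0("fs_", food_groups())])
  expect_equal(grp_sum, intake$free_sugar, tolerance = 1e-9)

  doubled <- sim$records
  doubled$amount <- doubled$amount * 2
  intake2 <- compute_intake(doubled, sim$nutrients)
  expect_equal(intake2$free_sugar, 2 * intake$free_sugar)
  expect_equal(intake2$energy, 2 * intake$energy)
  expect_equal(intake2$pct_free_sugar, intake$pct_free_sugar)
})

test_that("per-child intake equals a brute-force entry-by-entry recomputation", {
  cfg <- sim_config(n_children = 8)
  sim <- simulate_study(9, cfg)
  intake <- compute_intake(sim$records, sim$nutrients)
  for (cid in intake$child_id[1:4]) {
    rec <- sim$records[sim$records$child_id == cid, ]
    brute <- 0
    for (j in seq_len(nrow(rec))) {
      fs <- sim$nutrients$free_sugar[sim$nutrients$food_code == rec$food_code[j]]
      brute <- brute + unname(rec$amount[j]) / 100 * fs
    }
    brute <- brute / length(unique(rec$day_index))
    expect_equal(intake$free_sugar[intake$child_id == cid], brute,
                 tolerance = 1e-9)
  }
})

test_that("cohort intake table stratifies by excessive status with t-tests", {
  cfg <- sim_config(n_children = 60)
  sim <- simulate_study(13, cfg)
  intake <- compute_intake(sim$records, sim$nutrients)
  t3 <- suppressWarnings(cohort_intake_table(intake))
  expect_equal(t3$n, 60)
  expect_equal(t3$n_excessive + t3$n_non_excessive, 60)
  fs <- t3$nutrients[t3$nutrients$quantity == "free_sugar", ]
  # excessive children must eat more free sugar by construction
  expect_gt(fs$mean_excessive, fs$mean_non_excessive)
  # hand check of the stratified means
  expect_equal(fs$mean_excessive, mean(intake$free_sugar[intake$excessive]))
  tt <- two_sample_t(intake$free_sugar[intake$excessive],
                     intake$free_sugar[!intake$excessive])
  expect_equal(fs$p_value, tt$p_value)
  # shares average per-child percentages, not ratios of means
  shares <- t3$group_share
  expect_equal(sum(shares$mean_pct_contribution), 100, tolerance = 1e-6)
})
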