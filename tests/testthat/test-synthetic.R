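test_that("the whole simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_children = 30)
  s1 <- simulate_study(17, cfg)
  s2 <- simulate_study(17, cfg)
  expect_identical(s1$food_table, s2$food_table)
  expect_identical(s1$cohort_raw, s2$cohort_raw)
  expect_identical(s1$records, s2$records)
  s3 <- simulate_study(18, cfg)
  expect_false(identical(s1$records, s3$records))
})

test_that("default cohort reproduces the design margins exactly", {
  cohort <- gen_cohort(sim_config(), seed = 2)
  expect_equal(nrow(cohort$raw), 332)
  expect_equal(sum(cohort$raw$sex == "Boys"), 166)
  expect_equal(sum(cohort$raw$sex == "Girls"), 166)
  expect_equal(as.integer(table(cohort$raw$age_years)[c("3", "4", "5", "6")]),
               c(87L, 86L, 85L, 74L))
})

test_that("latent excessive probability is calibrated to the configured prevalence", {
  cfg <- sim_config()
  cohort <- gen_cohort(cfg, seed = 23)
  expect_equal(mean(cohort$truth$p_excessive), cfg$prevalence_target,
               tolerance = 1e-8)
  # the gamma tail above the threshold is the prevalence target itself
  expect_equal(cfg$prevalence_target,
               1 - pgamma(10, cfg$gamma_shape, cfg$gamma_rate))
  # percent-energy targets respect the latent flag by construction
  expect_true(all(cohort$truth$target_pct[cohort$truth$excessive] >= 10))
  expect_true(all(cohort$truth$target_pct[!cohort$truth$excessive] < 10))
})

test_that("synthetic food db exercises every assignment step at least once", {
  food <- gen_food_db(sim_config(), seed = 29)
  db <- build_sugar_db(food$food_table)
  expect_setequal(unique(db$total_step), 1:7)
  expect_setequal(unique(db$free_step), 1:11)
  expect_setequal(unique(db$food_group), food_groups())
})

test_that("generated records hit each child's energy and %E targets within 0.1%", {
  cfg <- sim_config(n_children = 50)
  sim <- simulate_study(37, cfg)
  intake <- compute_intake(sim$records, sim$nutrients)
  m <- dplyr::inner_join(intake, sim$cohort_truth, by = "child_id")
  expect_true(all(abs(m$energy / m$target_energy - 1) < 0.001))
  expect_true(all(abs(m$pct_free_sugar / m$target_pct - 1) < 0.001))
  expect_equal(m$excessive.x, m$excessive.y)
  # 3 days per child, two weekdays with school lunch and one weekend day
  days <- dplyr::count(sim$records, child_id, day_index, day_type)
  expect_equal(nrow(days), 150)
  expect_equal(sum(days$day_type == "weekend"), 50)
})

test_that("confectionaries are the leading free sugar source at defaults", {
  sim <- simulate_study(43, sim_config(n_children = 100))
  intake <- compute_intake(sim$records, sim$nutrients)
  t3 <- suppressWarnings(cohort_intake_table(intake))
  expect_equal(t3$group_share$food_group[1], "Confectionaries")
})

test_that("parameter recovery: fitted ORs track a configured screen-time effect", {
  # single strong effect, all else null: moderate n suffices
  cfg <- sim_config(n_children = 4000, log_or = "null")
  cfg$log_or$screen[">=1"] <- log(4.36)
  cohort <- gen_cohort(cfg, seed = 47)
  covs <- derive_covariates(cohort$raw)
  fit <- fit_excessive_model(covs, cohort$truth$excessive)
  est <- fit$estimates[fit$estimates$variable == "screen" &
                         fit$estimates$category == ">=1", ]
  expect_lt(abs(est$log_or - log(4.36)), 3 * est$se)
})

test_that("the end-to-end pipeline runs and writes a reproducible bundle", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- sim_config(n_children = 40)
  r1 <- suppressWarnings(run_study_pipeline(53, cfg, outdir = out1))
  r2 <- suppressWarnings(run_study_pipeline(53, cfg, outdir = out2))
  expect_true(file.exists(file.path(out1, "association_table.csv")))
  expect_identical(readLines(file.path(out1, "intake_summaries.csv")),
                   readLines(file.path(out2, "intake_summaries.csv")))
  expect_identical(readLines(file.path(out1, "provenance.txt")),
                   readLines(file.path(out2, "provenance.txt")))
  expect_equal(r1$prevalence, r2$prevalence)
  expect_s3_class(r1$association, "tbl_df")
})
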