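test_that("available carbohydrate subtracts fiber and clamps at zero", {
  expect_equal(available_carbohydrate(10, 2), 8)
  expect_equal(available_carbohydrate(75.5, 0), 75.5)
  expect_warning(v <- available_carbohydrate(1, 3, food_code = "X"), "X")
  expect_equal(v, 0)
  expect_error(available_carbohydrate(NA, 1, food_code = "BAD"), "BAD")
})

test_that("saccharide sum treats missingness as not-applicable, not zero", {
  expect_equal(sum_saccharides(c(1, 2, 0, 3, 0, 0)), 6)
  expect_equal(sum_saccharides(rep(0, 6)), 0)
  expect_true(is.na(sum_saccharides(c(NA, 2, 0, 3, 0, 0))))
  expect_error(sum_saccharides(c(-1, 2, 0, 3, 0, 0)), "negative")
})

test_that("monosaccharide-equivalent and dry-weight adjustments", {
  expect_equal(monosaccharide_equivalent_adjust(10), 9.5)
  expect_equal(monosaccharide_equivalent_adjust(0), 0)
  expect_equal(monosaccharide_equivalent_adjust(4.2), 3.99)
  expect_error(monosaccharide_equivalent_adjust(-1), "negative")

  expect_equal(dry_weight_adjust(7, 60, 60), 7)       # equal water: unchanged
  expect_equal(dry_weight_adjust(10, 90, 80), 20)     # dry-matter ratio 2
  expect_equal(dry_weight_adjust(10, 90, 80, cap = 15), 15)
  expect_equal(dry_weight_adjust(0, 30, 70), 0)
  expect_error(dry_weight_adjust(5, 100, 50), "water")
})

test_that("stepwise engine assigns hand-checkable items with provenance", {
  tbl <- tiny_food_table()
  db <- build_sugar_db(tbl)

  fruit <- db[db$food_code == "A1", ]
  expect_equal(fruit$total_sugar, 6)        # saccharide sum
  expect_equal(fruit$total_step, 1L)
  expect_equal(fruit$added_sugar, 0)        # intrinsic fruit sugar is neither
  expect_equal(fruit$free_sugar, 0)

  milk <- db[db$food_code == "A2", ]
  expect_equal(milk$total_sugar, 4.8)       # lactose only
  expect_equal(milk$added_sugar, 0)         # natural milk lactose excluded
  expect_equal(milk$free_sugar, 0)

  sugar <- db[db$food_code == "A3", ]
  expect_equal(sugar$total_sugar, 99)       # available carbohydrate
  expect_equal(sugar$total_step, 2L)
  expect_equal(sugar$added_sugar, 99)       # all sugar added
  expect_equal(sugar$free_sugar, 99)

  juice <- db[db$food_code == "A4", ]
  expect_equal(juice$total_sugar, 9.6)
  expect_equal(juice$added_sugar, 0)        # natural juice sugar is free...
  expect_equal(juice$free_sugar, 9.6)       # ...but not added
})

test_that("items without any usable data fall through to the residual steps", {
  tbl <- tiny_food_table()[1, ]
  tbl$glucose <- NA
  tbl$no_added_sugar <- FALSE
  db <- build_sugar_db(tbl)
  expect_equal(db$total_sugar, 0)
  expect_equal(db$total_step, 7L)
  expect_equal(db$free_step, 11L)
  expect_equal(db$free_sugar, 0)
})

test_that("unresolvable cross-references fall through with a warning; cycles error", {
  tbl <- tiny_food_table()
  tbl$glucose[1] <- NA
  tbl$ref_similar <- c("NOPE", NA, NA, NA)
  expect_warning(db <- build_sugar_db(tbl), "NOPE")
  expect_equal(db$total_step[1], 7L)

  cyc <- tiny_food_table()[1:2, ]
  cyc$glucose <- NA
  cyc$lactose <- NA
  cyc$ref_similar <- c("A2", "A1")
  expect_error(suppressWarnings(build_sugar_db(cyc)), "cyclic")
})

test_that("engine output is invariant to row order and idempotent", {
  cfg <- sim_config()
  food <- gen_food_db(cfg, seed = 7)
  db1 <- build_sugar_db(food$food_table)
  perm <- sample(nrow(food$food_table))
  db2 <- build_sugar_db(food$food_table[perm, ])
  expect_identical(db1[order(db1$food_code), ],
                   db2[order(db2$food_code), ])
  db3 <- build_sugar_db(food$food_table)
  expect_identical(db1, db3)  # bit-for-bit reproducible
})

test_that("stepwise engine recovers ground truth on the synthetic food db", {
  cfg <- sim_config()
  food <- gen_food_db(cfg, seed = 11)
  db <- build_sugar_db(food$food_table)
  tr <- dplyr::inner_join(db, food$truth, by = "food_code")
  expect_equal(tr$total_sugar, tr$true_total, tolerance = 1e-12)
  expect_equal(tr$added_sugar, tr$true_added, tolerance = 1e-12)
  expect_equal(tr$free_sugar, tr$true_free, tolerance = 1e-12)
  expect_equal(tr$total_step, tr$true_total_step)
  expect_equal(tr$free_step, tr$true_free_step)
})

test_that("sugar invariants hold and the validator reports injected violations", {
  cfg <- sim_config()
  food <- gen_food_db(cfg, seed = 3)
  db <- build_sugar_db(food$food_table)
  rep0 <- validate_sugar_db(db, food$food_table)
  expect_equal(nrow(rep0$violations), 0L)

  avail <- available_carbohydrate(food$food_table$carbohydrate,
                                  food$food_table$dietary_fiber)
  expect_true(all(db$added_sugar >= 0))
  expect_true(all(db$free_sugar >= db$added_sugar - 1e-9))
  expect_true(all(db$total_sugar >= db$free_sugar - 1e-9))
  expect_true(all(db$total_sugar <= avail + 1e-9))

  bad <- db
  bad$free_sugar[1] <- bad$total_sugar[1] + 5
  rep1 <- validate_sugar_db(bad, food$food_table)
  expect_equal(nrow(rep1$violations), 1L)
  expect_equal(rep1$violations$food_code, db$food_code[1])
  expect_equal(rep1$violations$rule, "free_gt_total")
})

test_that("single-item wrappers agree with the database build", {
  tbl <- tiny_food_table()
  one <- assign_total_sugar("A4", tbl)
  expect_equal(one$total_sugar, 9.6)
  expect_equal(one$total_step, 1L)
  af <- assign_added_free("A4", tbl)
  expect_equal(af$free_sugar, 9.6)
  expect_equal(af$free_step, 2L)
})

test_that("rule order is configurable and step ids follow the order", {
  tbl <- tiny_food_table()
  # literature ahead of the saccharide sum: a literature value must now win
  tbl$literature_total_sugar <- c(5.5, NA, NA, NA)
  rules <- sugar_rules(total_steps = c("literature", "saccharide_sum",
                                       "carbohydrate_all_sugar", "raw_form",
                                       "similar_item", "foreign_table", "zero"))
  db <- build_sugar_db(tbl, rules)
  expect_equal(db$total_sugar[db$food_code == "A1"], 5.5)
  expect_equal(db$total_step[db$food_code == "A1"], 1L)
  expect_error(sugar_rules(total_steps = c("zero", "saccharide_sum")), "zero")
})
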