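# Tiny hand-built food table used across the composition tests.
# avail carb: A1 = 8, A2 = 10, A3 = 99, A4 = 12
tiny_food_table <- function() {
  tibble::tibble(
    food_code = c("A1", "A2", "A3", "A4"),
    name = c("whole fruit", "plain milk", "table sugar", "fruit juice"),
    food_group = c("Fruits and vegetables", "Protein rich animal foods",
                   "Sugars and jams", "Fruit and vegetable juices"),
    energy = c(50, 63, 399, 45),
    protein = c(0.5, 3.3, 0, 0.5),
    fat = c(0.2, 3.8, 0, 0.1),
    saturated_fat = c(0, 2.3, 0, 0),
    carbohydrate = c(10, 10, 99, 12),
    dietary_fiber = c(2, 0, 0, 0),
    water = c(85, 87, 0.5, 88),
    glucose = c(1, 0, NA, 2),
    fructose = c(2, 0, NA, 3),
    galactose = c(0, 0, NA, 0),
    sucrose = c(3, 0, NA, 4.6),
    lactose = c(0, 4.8, NA, 0),
    maltose = c(0, 0, NA, 0),
    carbohydrate_is_all_sugar = c(FALSE, FALSE, TRUE, FALSE),
    no_added_sugar = c(TRUE, TRUE, FALSE, TRUE),
    all_sugar_added = c(FALSE, FALSE, TRUE, FALSE),
    is_fruit_juice_or_honey_or_syrup = c(FALSE, FALSE, FALSE, TRUE)
  )
}

# Two-food nutrient table for hand-checkable intake arithmetic.
tiny_nutrient_table <- function() {
  tibble::tibble(
    food_code = c("N1", "N2"),
    food_group = c("Confectionaries", "Cereals and potatoes"),
    energy = c(400, 150),
    protein = c(5, 3),
    fat = c(10, 1),
    saturated_fat = c(5, 0.3),
    carbohydrate = c(70, 32),
    total_sugar = c(40, 1),
    added_sugar = c(30, 0),
    free_sugar = c(30, 0)
  )
}

# adult thresholds for every age/sex: child classifier must then reduce to
# the adult one
adult_equivalent_cutoffs <- function() {
  expand.grid(age_years = 3:6, sex = c("Boys", "Girls"),
              stringsAsFactors = FALSE) |>
    dplyr::mutate(bmi_lower = 18.5, bmi_upper = 25)
}
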