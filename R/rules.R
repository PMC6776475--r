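#' Rule configuration for the stepwise sugar assignment engines
#'
#' The total-sugar engine tries an ordered list of estimation rules and the
#' first applicable rule wins; its position in the list is recorded as the
#' step provenance (1--7 by default). The added/free engine works the same
#' way over an 11-rule vocabulary. Step identifiers are therefore
#' configurable: reorder (or drop) rule names to change the stepwise
#' strategy without touching the estimators themselves.
#'
#' Default total-sugar order:
#' 1. `saccharide_sum` -- sum of the six mono- and disaccharides (glucose,
#'    fructose, galactose, sucrose, lactose, maltose) when all are known.
#' 2. `carbohydrate_all_sugar` -- available carbohydrate (carbohydrate minus
#'    dietary fiber) for items flagged as containing essentially only sugar.
#' 3. `literature` -- an analytical value taken from the literature.
#' 4. `raw_form` -- value of the linked raw (or otherwise referred) form,
#'    adjusted by the dry-weight ratio of the two items.
#' 5. `similar_item` -- value borrowed from a nutritionally similar item of
#'    the same family/order.
#' 6. `foreign_table` -- per-saccharide values from a foreign food
#'    composition table, with disaccharides multiplied by
#'    `mono_eq_factor` when the source expresses them as monosaccharide
#'    equivalents.
#' 7. `zero` -- 0 g/100 g for everything that remains.
#'
#' Default added/free-sugar order:
#' 1. `unprocessed_zero` -- unprocessed foods with no added sugar: added and
#'    free both 0 (intrinsic sugar of whole foods is neither).
#' 2. `natural_free` -- fruit juices, honey and syrups with no added sugar:
#'    added 0, free equal to total (their natural sugar counts as free).
#' 3. `all_added` -- items whose sugar is entirely added (table sugar,
#'    sweet syrup preparations): added = free = total.
#' 4. `label_value` -- analytical or label values for added (and optionally
#'    free) sugar.
#' 5. `recipe` -- proportion-weighted sum of the ingredient assignments.
#' 6. `similar_item` -- added/free fractions borrowed from a similar item
#'    and applied to the item's own total.
#' 7. `unsweetened_subtraction` -- total minus the total sugar of the linked
#'    unsweetened equivalent.
#' 8. `lactose_subtraction` -- total minus naturally occurring lactose
#'    (sweetened dairy).
#' 9. `proportion_fallback` -- `fallback_proportion` of total sugar for
#'    processed items with no better information.
#' 10. `foreign_table` -- added/free values from a foreign table.
#' 11. `zero` -- 0 g added and free for everything that remains.
#'
#' @param mono_eq_factor Factor applied to disaccharide values expressed as
#'   monosaccharide equivalents (default 0.95).
#' @param fallback_proportion Fraction of total sugar assigned as added/free
#'   by the `proportion_fallback` rule (default 0.5).
#' @param total_steps Character vector naming the total-sugar rules in the
#'   order they are tried.
#' @param free_steps Character vector naming the added/free rules in the
#'   order they are tried.
#' @return A list of class `sugar_rules`.
#' @export
#' @examples
#' rules <- sugar_rules()
#' rules$total_steps
sugar_rules <- function(mono_eq_factor = 0.95,
                        fallback_proportion = 0.5,
                        total_steps = c("saccharide_sum",
                                        "carbohydrate_all_sugar",
                                        "literature",
                                        "raw_form",
                                        "similar_item",
                                        "foreign_table",
                                        "zero"),
                        free_steps = c("unprocessed_zero",
                                       "natural_free",
                                       "all_added",
                                       "label_value",
                                       "recipe",
                                       "similar_item",
                                       "unsweetened_subtraction",
                                       "lactose_subtraction",
                                       "proportion_fallback",
                                       "foreign_table",
                                       "zero")) {
  stopifnot(is.numeric(mono_eq_factor), mono_eq_factor > 0, mono_eq_factor <= 1,
            is.numeric(fallback_proportion),
            fallback_proportion >= 0, fallback_proportion <= 1)
  if (utils::tail(total_steps, 1) != "zero") {
    stop("the final total-sugar rule must be 'zero' so that every item is assigned",
         call. = FALSE)
  }
  if (anyDuplicated(total_steps) || anyDuplicated(free_steps)) {
    stop("rule names must be unique within each engine", call. = FALSE)
  }
  structure(
    list(mono_eq_factor = mono_eq_factor,
         fallback_proportion = fallback_proportion,
         total_steps = total_steps,
         free_steps = free_steps),
    class = "sugar_rules"
  )
}

#' The ten food groups of the composition database
#'
#' Food groups follow culinary usage and nutrient-profile similarity as in
#' the national composition table the database is organised around.
#'
#' @return Character vector of the 10 group labels.
#' @export
food_groups <- function() {
  c("Cereals and potatoes",
    "Sugars and jams",
    "Pulses and nuts",
    "Fruits and vegetables",
    "Protein rich animal foods",
    "Confectionaries",
    "Fruit and vegetable juices",
    "Sugar-sweetened beverages",
    "Seasonings",
    "Other foods")
}

#' Names of the six mono- and disaccharides tracked per food
#' @return Character vector (monosaccharides first).
#' @export
saccharide_names <- function() {
  c("glucose", "fructose", "galactose", "sucrose", "lactose", "maltose")
}

# disaccharides among the six, used for monosaccharide-equivalent correction
disaccharide_names <- function() c("sucrose", "lactose", "maltose")
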