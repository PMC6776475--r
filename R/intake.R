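#' Nutrient totals for a set of dietary-record entries
#'
#' Composition-table arithmetic: each consumed amount contributes
#' `amount / 100 * content_per_100g` of every nutrient. Free sugar is also
#' accumulated by food group so that group contributions can be reported.
#'
#' @param entries Data frame of record entries with columns `child_id`,
#'   `day_index`, `food_code`, `amount` (g consumed, net of leftovers).
#' @param nutrient_db Food-level nutrient table: `food_code`, `food_group`,
#'   `energy`, `protein`, `fat`, `saturated_fat`, `carbohydrate`,
#'   `total_sugar`, `added_sugar`, `free_sugar` per 100 g (e.g. the food
#'   table joined with [build_sugar_db()] output).
#' @return Tibble with one row per `child_id` x `day_index`: nutrient totals
#'   plus one `fs_<group>` column per food group (free sugar g from that
#'   group).
#' @export
daily_intake <- function(entries, nutrient_db) {
  unknown <- setdiff(unique(entries$food_code), nutrient_db$food_code)
  if (length(unknown)) {
    stop("dietary record contains unresolvable food codes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(entries$amount < 0)) stop("negative consumed amount", call. = FALSE)
  nutrients <- c("energy", "protein", "fat", "saturated_fat", "carbohydrate",
                 "total_sugar", "added_sugar", "free_sugar")
  joined <- dplyr::left_join(entries, nutrient_db, by = "food_code")
  day <- joined |>
    dplyr::group_by(.data$child_id, .data$day_index) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(nutrients),
                                   ~ sum(.data$amount / 100 * .x)),
                     .groups = "drop")
  groups <- joined |>
    dplyr::group_by(.data$child_id, .data$day_index, .data$food_group) |>
    dplyr::summarise(fs = sum(.data$amount / 100 * .data$free_sugar),
                     .groups = "drop") |>
    dplyr::mutate(food_group = paste0("fs_", .data$food_group)) |>
    tidyr::pivot_wider(names_from = "food_group", values_from = "fs",
                       values_fill = 0)
  for (g in paste0("fs_", food_groups())) {
    if (!g %in% names(groups)) groups[[g]] <- 0
  }
  dplyr::left_join(day, groups, by = c("child_id", "day_index"))
}

#' Per-child mean daily intake over the recorded days
#'
#' Averages the day-level totals of [daily_intake()] within child. The
#' default is the unweighted mean over the recorded days (normally 3: two
#' weekdays with a nursery-school lunch and one weekend day); optional day
#' weights are available for sensitivity analyses.
#'
#' @param day_totals Output of [daily_intake()].
#' @param day_weights Optional numeric vector of weights, one per
#'   `day_index` in ascending order; normalised internally.
#' @return Tibble, one row per child, with mean daily values of every
#'   nutrient and `fs_<group>` column.
#' @export
mean_daily_intake <- function(day_totals, day_weights = NULL) {
  if (!nrow(day_totals)) stop("no recorded days", call. = FALSE)
  value_cols <- setdiff(names(day_totals), c("child_id", "day_index"))
  if (is.null(day_weights)) {
    day_totals |>
      dplyr::group_by(.data$child_id) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(value_cols), mean),
                       .groups = "drop")
  } else {
    di <- sort(unique(day_totals$day_index))
    if (length(day_weights) != length(di)) {
      stop("day_weights must have one weight per recorded day index", call. = FALSE)
    }
    w <- day_weights / sum(day_weights)
    wt <- w[match(day_totals$day_index, di)]
    day_totals |>
      dplyr::mutate(.w = wt) |>
      dplyr::group_by(.data$child_id) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(value_cols),
                                     ~ sum(.x * .data$.w) / sum(.data$.w)),
                       .groups = "drop")
  }
}

#' Percentage of energy supplied by a nutrient
#'
#' `grams * kcal_per_gram / energy * 100`. Energy conversion factors default
#' to the Atwater values: 4 kcal/g for carbohydrate, sugars and protein,
#' 9 kcal/g for fat.
#'
#' @param grams_per_day Mean daily intake, g/d.
#' @param energy Mean daily energy, kcal/d; must be positive.
#' @param kcal_per_gram Energy factor, kcal/g (default 4).
#' @return Percent of energy.
#' @export
#' @examples
#' percent_energy(50, 2000) # 10
percent_energy <- function(grams_per_day, energy, kcal_per_gram = 4) {
  if (any(energy <= 0)) stop("energy must be positive", call. = FALSE)
  grams_per_day * kcal_per_gram / energy * 100
}

#' Classify excessive free sugar intake (WHO threshold)
#'
#' Free sugar supplying at least 10% of energy intake is excessive; the
#' bound is closed from below.
#'
#' @param free_sugar_pct_energy Percent of energy from free sugar.
#' @param threshold Threshold in percent of energy (default 10).
#' @return Logical vector.
#' @export
#' @examples
#' classify_excessive(c(6.5, 10, 12.4)) # FALSE TRUE TRUE
classify_excessive <- function(free_sugar_pct_energy, threshold = 10) {
  if (any(free_sugar_pct_energy < 0, na.rm = TRUE)) {
    stop("negative percent of energy", call. = FALSE)
  }
  free_sugar_pct_energy >= threshold
}

#' Per-child intake summaries from dietary records
#'
#' Full intake pipeline: day totals, per-child means, percent-of-energy
#' values for every energy-providing nutrient, and the excessive-intake
#' flag.
#'
#' @inheritParams daily_intake
#' @inheritParams mean_daily_intake
#' @param kcal_factors Named energy factors (kcal/g) for `protein`, `fat`,
#'   `saturated_fat`, `carbohydrate` and the sugars.
#' @param threshold Excessive-intake threshold, percent of energy.
#' @return Tibble, one row per child: g/d intakes, `fs_<group>` free sugar
#'   by group, `pct_*` percent-of-energy columns and `excessive`.
#' @export
compute_intake <- function(entries, nutrient_db, day_weights = NULL,
                           kcal_factors = c(protein = 4, fat = 9,
                                            saturated_fat = 9, carbohydrate = 4,
                                            sugar = 4),
                           threshold = 10) {
  means <- mean_daily_intake(daily_intake(entries, nutrient_db), day_weights)
  means |>
    dplyr::mutate(
      pct_protein = percent_energy(.data$protein, .data$energy, kcal_factors[["protein"]]),
      pct_fat = percent_energy(.data$fat, .data$energy, kcal_factors[["fat"]]),
      pct_saturated_fat = percent_energy(.data$saturated_fat, .data$energy,
                                         kcal_factors[["saturated_fat"]]),
      pct_carbohydrate = percent_energy(.data$carbohydrate, .data$energy,
                                        kcal_factors[["carbohydrate"]]),
      pct_total_sugar = percent_energy(.data$total_sugar, .data$energy,
                                       kcal_factors[["sugar"]]),
      pct_added_sugar = percent_energy(.data$added_sugar, .data$energy,
                                       kcal_factors[["sugar"]]),
      pct_free_sugar = percent_energy(.data$free_sugar, .data$energy,
                                      kcal_factors[["sugar"]]),
      excessive = classify_excessive(.data$pct_free_sugar, threshold)
    )
}

#' Prevalence of excessive free sugar intake
#'
#' @param summaries Output of [compute_intake()] (or any data frame with a
#'   logical `excessive` column).
#' @return Percentage, full precision (round at report time).
#' @export
#' @examples
#' prevalence_excessive(data.frame(excessive = rep(c(TRUE, FALSE), c(72, 260))))
prevalence_excessive <- function(summaries) {
  if (!nrow(summaries)) stop("empty cohort", call. = FALSE)
  100 * mean(summaries$excessive)
}

#' Cohort dietary intake table (overall and by excessive status)
#'
#' Mean and SD of every intake quantity overall and within the excessive /
#' non-excessive strata, with two-sample t-test p-values for the group
#' difference, plus the mean per-child percentage contribution of each food
#' group to free sugar intake. Group contributions are averaged per child
#' (mean of per-child percentages), not taken as a ratio of means.
#'
#' @param summaries Output of [compute_intake()].
#' @param welch Use Welch's t-test instead of the pooled-variance test.
#' @return A list with `nutrients` (tibble: quantity, overall/excessive/
#'   non-excessive mean and SD, p-value) and `group_share` (tibble:
#'   food_group, mean per-child percent contribution to free sugar).
#' @export
cohort_intake_table <- function(summaries, welch = FALSE) {
  quantities <- c("free_sugar", paste0("fs_", food_groups()), "energy",
                  "pct_protein", "pct_fat", "pct_saturated_fat",
                  "pct_carbohydrate", "pct_total_sugar", "pct_added_sugar",
                  "pct_free_sugar")
  exc <- summaries$excessive
  n_exc <- sum(exc); n_non <- sum(!exc)
  if (n_exc == 0 || n_non == 0) {
    warning("empty excessive or non-excessive stratum: group tests omitted",
            call. = FALSE)
  }
  rows <- lapply(quantities, function(q) {
    x <- summaries[[q]]
    p <- if (n_exc >= 2 && n_non >= 2) {
      tt <- two_sample_t(x[exc], x[!exc], equal_variance = !welch)
      tt$p_value
    } else NA_real_
    tibble::tibble(
      quantity = q,
      mean = mean(x), sd = stats::sd(x),
      mean_excessive = if (n_exc) mean(x[exc]) else NA_real_,
      sd_excessive = if (n_exc > 1) stats::sd(x[exc]) else NA_real_,
      mean_non_excessive = if (n_non) mean(x[!exc]) else NA_real_,
      sd_non_excessive = if (n_non > 1) stats::sd(x[!exc]) else NA_real_,
      p_value = p
    )
  })
  share <- sapply(food_groups(), function(g) {
    mean(ifelse(summaries$free_sugar > 0,
                100 * summaries[[paste0("fs_", g)]] / summaries$free_sugar, 0))
  })
  list(
    nutrients = dplyr::bind_rows(rows),
    group_share = tibble::tibble(food_group = food_groups(),
                                 mean_pct_contribution = unname(share)) |>
      dplyr::arrange(dplyr::desc(.data$mean_pct_contribution)),
    n = nrow(summaries), n_excessive = n_exc, n_non_excessive = n_non
  )
}
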