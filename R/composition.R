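#' Available carbohydrate of a food
#'
#' Available carbohydrate is total carbohydrate minus dietary fiber, per
#' 100 g of edible portion. It bounds every sugar value the stepwise engine
#' can assign: a food cannot contain more sugar than available carbohydrate.
#'
#' @param carbohydrate Carbohydrate, g/100 g. Vectorised.
#' @param dietary_fiber Dietary fiber, g/100 g. Vectorised.
#' @param food_code Optional identifier(s) used in messages.
#' @return Numeric vector, g/100 g, clamped at 0 (with a warning) where
#'   fiber exceeds carbohydrate.
#' @export
#' @examples
#' available_carbohydrate(10, 2)   # 8
#' available_carbohydrate(75.5, 0) # 75.5
available_carbohydrate <- function(carbohydrate, dietary_fiber, food_code = NULL) {
  if (any(is.na(carbohydrate))) {
    bad <- if (is.null(food_code)) which(is.na(carbohydrate)) else food_code[is.na(carbohydrate)]
    stop("missing carbohydrate for: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  dietary_fiber[is.na(dietary_fiber)] <- 0
  out <- carbohydrate - dietary_fiber
  neg <- out < 0
  if (any(neg)) {
    lab <- if (is.null(food_code)) which(neg) else food_code[neg]
    warning("dietary fiber exceeds carbohydrate (clamped to 0) for: ",
            paste(lab, collapse = ", "), call. = FALSE)
    out[neg] <- 0
  }
  out
}

#' Sum the six mono- and disaccharides
#'
#' Total sugar is the sum of glucose, fructose, galactose, sucrose, lactose
#' and maltose. A missing saccharide makes the sum not applicable (returns
#' `NA`): missingness is a distinct state from 0 and drives step fallthrough
#' in the engine, it is never silently treated as zero.
#'
#' @param profile Numeric vector or one-row data frame holding the six
#'   saccharides (order/names as [saccharide_names()]).
#' @return The sum, or `NA_real_` if any component is missing.
#' @export
sum_saccharides <- function(profile) {
  if (is.data.frame(profile)) profile <- unlist(profile[1, saccharide_names()])
  profile <- as.numeric(profile)
  if (length(profile) != 6L) stop("expected six saccharide values", call. = FALSE)
  if (anyNA(profile)) return(NA_real_)
  if (any(profile < 0)) stop("negative saccharide value", call. = FALSE)
  sum(profile)
}

#' Monosaccharide-equivalent correction for disaccharide values
#'
#' Some foreign composition tables express disaccharides as monosaccharide
#' equivalents; multiplying by 0.95 converts back to disaccharide mass.
#'
#' @param value Disaccharide value(s), g/100 g.
#' @param factor Correction factor, default 0.95.
#' @return `value * factor`.
#' @export
#' @examples
#' monosaccharide_equivalent_adjust(10) # 9.5
monosaccharide_equivalent_adjust <- function(value, factor = 0.95) {
  if (any(value < 0, na.rm = TRUE)) stop("negative disaccharide value", call. = FALSE)
  value * factor
}

#' Dry-weight adjustment when borrowing a value from another item
#'
#' A value referred from another food (e.g. the raw form of a cooked item)
#' is rescaled by the ratio of dry matter: `value * (100 - water_target) /
#' (100 - water_referred)`, then capped at `cap` (normally the target item's
#' available carbohydrate).
#'
#' @param value Referred value, g/100 g.
#' @param water_referred,water_target Water contents, g/100 g; must be < 100
#'   for the referred item.
#' @param cap Upper cap applied after adjustment (default `Inf`).
#' @return Adjusted value, g/100 g.
#' @export
#' @examples
#' dry_weight_adjust(10, water_referred = 90, water_target = 80) # 20
dry_weight_adjust <- function(value, water_referred, water_target, cap = Inf) {
  if (any(water_referred >= 100)) {
    stop("referred item has water content >= 100 g/100 g", call. = FALSE)
  }
  pmin(value * (100 - water_target) / (100 - water_referred), cap)
}

# --- internal engine machinery ------------------------------------------

# Tolerant column access: optional columns may be absent from the table.
fcol <- function(tbl, name, default = NA) {
  if (name %in% names(tbl)) tbl[[name]] else rep(default, nrow(tbl))
}

flag_col <- function(tbl, name) {
  v <- fcol(tbl, name, default = FALSE)
  v[is.na(v)] <- FALSE
  as.logical(v)
}

check_food_table <- function(food_tbl) {
  req <- c("food_code", "food_group", "energy", "carbohydrate", "dietary_fiber", "water")
  missing_cols <- setdiff(req, names(food_tbl))
  if (length(missing_cols)) {
    stop("food table lacks required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(food_tbl$food_code)) {
    stop("duplicated food_code in food table", call. = FALSE)
  }
  bad_group <- setdiff(unique(food_tbl$food_group), food_groups())
  if (length(bad_group)) {
    stop("unknown food group(s): ", paste(bad_group, collapse = ", "), call. = FALSE)
  }
  invisible(food_tbl)
}

parse_recipe <- function(txt) {
  # "CODE:prop;CODE:prop" -> data.frame(food_code, proportion)
  if (is.na(txt) || !nzchar(txt)) return(NULL)
  parts <- strsplit(strsplit(txt, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  codes <- vapply(parts, `[`, character(1), 1L)
  props <- as.numeric(vapply(parts, `[`, character(1), 2L))
  if (anyNA(props) || any(props < 0)) {
    stop("malformed recipe specification: ", txt, call. = FALSE)
  }
  data.frame(food_code = codes, proportion = props, stringsAsFactors = FALSE)
}

# Environment-based resolver for total sugar with memoisation and cycle
# detection. Returns list(total, step) per food code.
make_total_resolver <- function(food_tbl, rules) {
  idx <- stats::setNames(seq_len(nrow(food_tbl)), food_tbl$food_code)
  sac <- as.matrix(food_tbl[, intersect(saccharide_names(), names(food_tbl)), drop = FALSE])
  if (ncol(sac) < 6L) {
    full <- matrix(NA_real_, nrow(food_tbl), 6, dimnames = list(NULL, saccharide_names()))
    full[, colnames(sac)] <- sac
    sac <- full
  } else {
    sac <- sac[, saccharide_names(), drop = FALSE]
  }
  foreign_cols <- paste0("foreign_", saccharide_names())
  fsac <- sapply(foreign_cols, function(nm) as.numeric(fcol(food_tbl, nm, NA_real_)))
  fsac <- matrix(fsac, nrow = nrow(food_tbl), dimnames = list(NULL, saccharide_names()))

  avail <- available_carbohydrate(food_tbl$carbohydrate, food_tbl$dietary_fiber,
                                  food_tbl$food_code)
  lit <- as.numeric(fcol(food_tbl, "literature_total_sugar", NA_real_))
  all_sugar <- flag_col(food_tbl, "carbohydrate_is_all_sugar")
  ref_raw <- as.character(fcol(food_tbl, "ref_raw_form", NA_character_))
  ref_sim <- as.character(fcol(food_tbl, "ref_similar", NA_character_))
  mono_eq <- flag_col(food_tbl, "foreign_mono_eq")
  water <- food_tbl$water

  memo <- new.env(parent = emptyenv())
  in_progress <- new.env(parent = emptyenv())

  resolve_ref <- function(code, who) {
    if (is.na(code)) return(NULL)
    if (!code %in% names(idx)) {
      warning("food ", who, " refers to unknown item ", code,
              "; rule skipped", call. = FALSE)
      return(NULL)
    }
    resolve(code)
  }

  resolve <- function(code) {
    if (!is.null(memo[[code]])) return(memo[[code]])
    if (!is.null(in_progress[[code]])) {
      stop("cyclic cross-reference involving food ", code, call. = FALSE)
    }
    in_progress[[code]] <- TRUE
    on.exit(rm(list = code, envir = in_progress), add = TRUE)
    i <- idx[[code]]
    res <- NULL
    for (k in seq_along(rules$total_steps)) {
      rule <- rules$total_steps[[k]]
      val <- switch(
        rule,
        saccharide_sum = if (!anyNA(sac[i, ])) sum(sac[i, ]) else NA_real_,
        carbohydrate_all_sugar = if (all_sugar[i]) avail[i] else NA_real_,
        literature = lit[i],
        raw_form = {
          r <- resolve_ref(ref_raw[i], code)
          if (is.null(r)) NA_real_ else {
            dry_weight_adjust(r$total, water_referred = water[idx[[ref_raw[i]]]],
                              water_target = water[i])
          }
        },
        similar_item = {
          r <- resolve_ref(ref_sim[i], code)
          if (is.null(r)) NA_real_ else r$total
        },
        foreign_table = {
          v <- fsac[i, ]
          if (anyNA(v)) NA_real_ else {
            dis <- disaccharide_names()
            if (mono_eq[i]) {
              v[dis] <- monosaccharide_equivalent_adjust(v[dis], rules$mono_eq_factor)
            }
            sum(v)
          }
        },
        zero = 0,
        stop("unknown total-sugar rule: ", rule, call. = FALSE)
      )
      if (!is.na(val)) {
        res <- list(total = min(max(val, 0), avail[i]), step = k)
        break
      }
    }
    if (is.null(res)) {
      stop("no total-sugar rule applied to food ", code,
           " (rule set must end in 'zero')", call. = FALSE)
    }
    memo[[code]] <- res
    res
  }
  list(resolve = resolve, avail = avail, idx = idx)
}

# Resolver for added/free sugar given the total-sugar results.
make_free_resolver <- function(food_tbl, totals, rules, avail, idx) {
  juice_flag <- flag_col(food_tbl, "is_fruit_juice_or_honey_or_syrup")
  no_added <- flag_col(food_tbl, "no_added_sugar")
  all_added <- flag_col(food_tbl, "all_sugar_added")
  processed <- flag_col(food_tbl, "processed")
  lactose <- as.numeric(fcol(food_tbl, "lactose", NA_real_))
  lab_added <- as.numeric(fcol(food_tbl, "label_added_sugar", NA_real_))
  lab_free <- as.numeric(fcol(food_tbl, "label_free_sugar", NA_real_))
  for_added <- as.numeric(fcol(food_tbl, "foreign_added_sugar", NA_real_))
  for_free <- as.numeric(fcol(food_tbl, "foreign_free_sugar", NA_real_))
  ref_sim <- as.character(fcol(food_tbl, "ref_similar", NA_character_))
  ref_unsw <- as.character(fcol(food_tbl, "ref_unsweetened", NA_character_))
  recipes <- as.character(fcol(food_tbl, "recipe", NA_character_))

  memo <- new.env(parent = emptyenv())
  in_progress <- new.env(parent = emptyenv())

  resolve <- function(code) {
    if (!is.null(memo[[code]])) return(memo[[code]])
    if (!is.null(in_progress[[code]])) {
      stop("cyclic cross-reference involving food ", code, call. = FALSE)
    }
    in_progress[[code]] <- TRUE
    on.exit(rm(list = code, envir = in_progress), add = TRUE)
    i <- idx[[code]]
    tot <- totals$total[i]
    res <- NULL
    for (k in seq_along(rules$free_steps)) {
      rule <- rules$free_steps[[k]]
      pair <- switch(
        rule,
        unprocessed_zero = if (no_added[i] && !juice_flag[i]) c(0, 0) else NULL,
        natural_free = if (no_added[i] && juice_flag[i]) c(0, tot) else NULL,
        all_added = if (all_added[i]) c(tot, tot) else NULL,
        label_value = if (!is.na(lab_added[i])) {
          c(lab_added[i], if (!is.na(lab_free[i])) lab_free[i] else lab_added[i])
        } else NULL,
        recipe = {
          rec <- parse_recipe(recipes[i])
          if (is.null(rec)) NULL else if (!all(rec$food_code %in% names(idx))) {
            warning("recipe of ", code, " refers to unknown item(s); rule skipped",
                    call. = FALSE)
            NULL
          } else {
            parts <- lapply(rec$food_code, resolve)
            c(sum(rec$proportion * vapply(parts, `[[`, numeric(1), "added")),
              sum(rec$proportion * vapply(parts, `[[`, numeric(1), "free")))
          }
        },
        similar_item = if (!is.na(ref_sim[i])) {
          if (!ref_sim[i] %in% names(idx)) {
            warning("food ", code, " refers to unknown item ", ref_sim[i],
                    "; rule skipped", call. = FALSE)
            NULL
          } else {
            s <- resolve(ref_sim[i])
            st <- totals$total[idx[[ref_sim[i]]]]
            if (st > 0) c(tot * s$added / st, tot * s$free / st) else c(0, 0)
          }
        } else NULL,
        unsweetened_subtraction = if (!is.na(ref_unsw[i])) {
          if (!ref_unsw[i] %in% names(idx)) {
            warning("food ", code, " refers to unknown item ", ref_unsw[i],
                    "; rule skipped", call. = FALSE)
            NULL
          } else {
            base <- totals$total[idx[[ref_unsw[i]]]]
            add <- max(tot - base, 0)
            c(add, if (juice_flag[i]) tot else add)
          }
        } else NULL,
        lactose_subtraction = if (!is.na(lactose[i]) && lactose[i] > 0) {
          v <- max(tot - lactose[i], 0)
          c(v, v)
        } else NULL,
        proportion_fallback = if (processed[i]) {
          v <- rules$fallback_proportion * tot
          c(v, v)
        } else NULL,
        foreign_table = if (!is.na(for_added[i])) {
          c(for_added[i], if (!is.na(for_free[i])) for_free[i] else for_added[i])
        } else NULL,
        zero = c(0, 0),
        stop("unknown added/free rule: ", rule, call. = FALSE)
      )
      if (!is.null(pair)) {
        added <- min(max(pair[1], 0), tot)
        free <- min(max(pair[2], added), tot)
        if (abs(added - pair[1]) > 1e-9 || abs(free - pair[2]) > 1e-9) {
          warning("added/free sugar of ", code,
                  " clamped to satisfy added <= free <= total", call. = FALSE)
        }
        res <- list(added = added, free = free, step = k)
        break
      }
    }
    if (is.null(res)) {
      stop("no added/free rule applied to food ", code, call. = FALSE)
    }
    memo[[code]] <- res
    res
  }
  resolve
}

#' Build the total/added/free sugar database with step provenance
#'
#' Runs the 7-step total-sugar engine and the 11-step added/free engine over
#' a food composition table and returns one assignment per item together
#' with the step that produced each value. Missing data are a distinct state
#' from zero; only the final residual rule converts absence into 0 g.
#'
#' The food table is a data frame with one row per item. Required columns:
#' `food_code`, `food_group` (one of [food_groups()]), `energy`,
#' `carbohydrate`, `dietary_fiber`, `water` (all per 100 g). Optional
#' columns consumed by the rules: the six saccharides
#' ([saccharide_names()]); logical flags `carbohydrate_is_all_sugar`,
#' `no_added_sugar`, `all_sugar_added`, `is_fruit_juice_or_honey_or_syrup`,
#' `processed`; `literature_total_sugar`, `label_added_sugar`,
#' `label_free_sugar`; cross-references `ref_raw_form`, `ref_similar`,
#' `ref_unsweetened` (food codes); `foreign_<saccharide>` values with
#' `foreign_mono_eq`, `foreign_added_sugar`, `foreign_free_sugar`; and
#' `recipe` (`"CODE:prop;CODE:prop"`). Empty cells are missing values,
#' never 0.
#'
#' @param food_tbl Food composition table (see Details).
#' @param rules A [sugar_rules()] object.
#' @return A tibble with columns `food_code`, `food_group`, `total_sugar`,
#'   `added_sugar`, `free_sugar` (g/100 g, full precision), `total_step`
#'   and `free_step` (integer step provenance).
#' @export
#' @examples
#' tbl <- tibble::tibble(
#'   food_code = c("F1", "F2"), name = c("apple", "cola"),
#'   food_group = c("Fruits and vegetables", "Sugar-sweetened beverages"),
#'   energy = c(54, 46), carbohydrate = c(14.1, 11.4),
#'   dietary_fiber = c(1.9, 0), water = c(84, 88),
#'   glucose = c(1.4, NA), fructose = c(6.3, NA), galactose = c(0, NA),
#'   sucrose = c(4.8, NA), lactose = c(0, NA), maltose = c(0, NA),
#'   carbohydrate_is_all_sugar = c(FALSE, TRUE),
#'   no_added_sugar = c(TRUE, FALSE), processed = c(FALSE, TRUE)
#' )
#' build_sugar_db(tbl)
build_sugar_db <- function(food_tbl, rules = sugar_rules()) {
  check_food_table(food_tbl)
  tot_engine <- make_total_resolver(food_tbl, rules)
  totals <- lapply(food_tbl$food_code, tot_engine$resolve)
  tot_df <- data.frame(total = vapply(totals, `[[`, numeric(1), "total"),
                       step = vapply(totals, `[[`, integer(1), "step"))
  free_engine <- make_free_resolver(food_tbl, tot_df, rules,
                                    tot_engine$avail, tot_engine$idx)
  frees <- lapply(food_tbl$food_code, free_engine)
  tibble::tibble(
    food_code = food_tbl$food_code,
    food_group = food_tbl$food_group,
    total_sugar = tot_df$total,
    added_sugar = vapply(frees, `[[`, numeric(1), "added"),
    free_sugar = vapply(frees, `[[`, numeric(1), "free"),
    total_step = tot_df$step,
    free_step = vapply(frees, `[[`, integer(1), "step")
  )
}

#' Single-item total sugar assignment
#'
#' Convenience wrapper around [build_sugar_db()] resolving one item (and,
#' recursively, anything it refers to).
#'
#' @param food_code Code of the item of interest.
#' @param food_tbl Food composition table.
#' @param rules A [sugar_rules()] object.
#' @return A list with `total_sugar` and `total_step`.
#' @export
assign_total_sugar <- function(food_code, food_tbl, rules = sugar_rules()) {
  check_food_table(food_tbl)
  eng <- make_total_resolver(food_tbl, rules)
  if (!food_code %in% food_tbl$food_code) {
    stop("unknown food_code: ", food_code, call. = FALSE)
  }
  r <- eng$resolve(food_code)
  list(total_sugar = r$total, total_step = r$step)
}

#' Single-item added/free sugar assignment
#'
#' @inheritParams assign_total_sugar
#' @return A list with `added_sugar`, `free_sugar` and `free_step`.
#' @export
assign_added_free <- function(food_code, food_tbl, rules = sugar_rules()) {
  db <- build_sugar_db(food_tbl, rules)
  row <- db[db$food_code == food_code, ]
  if (!nrow(row)) stop("unknown food_code: ", food_code, call. = FALSE)
  list(added_sugar = row$added_sugar, free_sugar = row$free_sugar,
       free_step = row$free_step)
}

#' Validate a sugar database and tabulate step provenance
#'
#' Report-only check of the physical invariants `0 <= added <= free <=
#' total <= available carbohydrate` plus per-step item counts by food group
#' (the layout used to summarise the stepwise development of the database).
#'
#' @param assignments Output of [build_sugar_db()].
#' @param food_tbl The food table the assignments were built from.
#' @param tol Numeric tolerance for the invariant chain (default 1e-9).
#' @return A list with `violations` (tibble: `food_code`, `rule`, `detail`)
#'   and `step_counts` (tibble: `food_group`, `engine`, `step`, `n`).
#' @export
validate_sugar_db <- function(assignments, food_tbl, tol = 1e-9) {
  stopifnot(all(assignments$food_code %in% food_tbl$food_code))
  m <- match(assignments$food_code, food_tbl$food_code)
  avail <- available_carbohydrate(food_tbl$carbohydrate[m],
                                  food_tbl$dietary_fiber[m],
                                  food_tbl$food_code[m])
  viol <- list()
  flag <- function(cond, rule, detail) {
    if (any(cond)) {
      viol[[length(viol) + 1L]] <<- tibble::tibble(
        food_code = assignments$food_code[cond], rule = rule,
        detail = detail[cond])
    }
  }
  flag(assignments$added_sugar < -tol, "negative_added",
       sprintf("added = %g", assignments$added_sugar))
  flag(assignments$free_sugar < assignments$added_sugar - tol, "added_gt_free",
       sprintf("added = %g > free = %g", assignments$added_sugar, assignments$free_sugar))
  flag(assignments$total_sugar < assignments$free_sugar - tol, "free_gt_total",
       sprintf("free = %g > total = %g", assignments$free_sugar, assignments$total_sugar))
  flag(assignments$total_sugar > avail + tol, "total_gt_available_carbohydrate",
       sprintf("total = %g > available = %g", assignments$total_sugar, avail))
  violations <- if (length(viol)) dplyr::bind_rows(viol) else
    tibble::tibble(food_code = character(), rule = character(), detail = character())

  counts <- dplyr::bind_rows(
    dplyr::count(dplyr::mutate(assignments, engine = "total", step = .data$total_step),
                 .data$food_group, .data$engine, .data$step),
    dplyr::count(dplyr::mutate(assignments, engine = "added_free", step = .data$free_step),
                 .data$food_group, .data$engine, .data$step)
  )
  list(violations = violations, step_counts = counts)
}
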