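#' Crude odds ratio with Wald confidence interval from a 2x2 table
#'
#' Cross-product odds ratio of a comparison category against a reference
#' category, with the Wald interval on the log-odds scale:
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` where `a`/`b` are
#' cases/non-cases in the comparison category and `c`/`d` in the reference.
#' With any zero cell the estimate is undefined (rendered as a dash in
#' reports) unless the Haldane--Anscombe continuity correction is requested.
#'
#' @param n_ref,x_ref Total and case counts in the reference category.
#' @param n_cmp,x_cmp Total and case counts in the comparison category.
#' @param z Critical value (default 1.959964, two-sided 95%).
#' @param continuity_correction Add 0.5 to every cell when any cell is zero
#'   instead of returning an undefined result.
#' @return List: `or`, `ci_low`, `ci_high`, `log_se`, `defined`.
#' @export
#' @examples
#' crude_or_ci(n_ref = 44, x_ref = 3, n_cmp = 173, x_cmp = 39)
crude_or_ci <- function(n_ref, x_ref, n_cmp, x_cmp, z = 1.959964,
                        continuity_correction = FALSE) {
  stopifnot(x_ref >= 0, x_cmp >= 0, x_ref <= n_ref, x_cmp <= n_cmp)
  a <- x_cmp; b <- n_cmp - x_cmp; c <- x_ref; d <- n_ref - x_ref
  if (min(a, b, c, d) == 0) {
    if (!continuity_correction) {
      return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  log_se = NA_real_, defined = FALSE))
    }
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
       log_se = se, defined = TRUE)
}

#' Two-sample t-test for a group difference
#'
#' Classical independent-samples t-test, pooled variance by default, Welch
#' by flag. Degenerate input (zero variance in both groups with equal
#' means) yields an undefined p-value with a warning.
#'
#' @param x,y Numeric samples, each of length at least 2.
#' @param equal_variance Pooled-variance test (default) or Welch.
#' @return List: `t`, `df`, `p_value`.
#' @export
two_sample_t <- function(x, y, equal_variance = TRUE) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      warning("both groups constant and equal: t-test undefined", call. = FALSE)
      return(list(t = NA_real_, df = NA_real_, p_value = NA_real_))
    }
  }
  tt <- stats::t.test(x, y, var.equal = equal_variance)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Multivariable logistic model for excessive intake
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()]) with all covariates entered simultaneously
#' under reference-level indicator coding. Adjusted odds ratios are
#' `exp(coefficient)` with Wald intervals from the observed information.
#' Perfect separation is detected from diverging coefficients / exploding
#' standard errors and the affected odds ratios are reported undefined.
#' Constant covariates are dropped with a warning.
#'
#' @param covariates Data frame of factor covariates (e.g. from
#'   [derive_covariates()]; a `child_id` column is ignored).
#' @param outcome Logical or 0/1 vector, one per row of `covariates`.
#' @param z Critical value for the Wald intervals.
#' @return List with `estimates` (tibble: `variable`, `category`,
#'   `reference`, `or`, `ci_low`, `ci_high`, `log_or`, `se`, `defined`),
#'   `fit` (the `glm` object), `converged`, and `gradient_norm` (score
#'   norm at the optimum).
#' @export
fit_excessive_model <- function(covariates, outcome, z = 1.959964) {
  dat <- dplyr::select(tibble::as_tibble(covariates),
                       -dplyr::any_of("child_id"))
  stopifnot(nrow(dat) == length(outcome))
  keep <- vapply(dat, function(v) length(unique(v[!is.na(v)])) > 1, logical(1))
  if (!all(keep)) {
    warning("constant covariate(s) dropped: ",
            paste(names(dat)[!keep], collapse = ", "), call. = FALSE)
    dat <- dat[, keep, drop = FALSE]
  }
  dat <- droplevels(dat)
  y <- as.integer(outcome)
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = cbind(y = y, dat), family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  X <- stats::model.matrix(fit)
  p <- stats::fitted(fit)
  grad <- drop(crossprod(X, y - p))
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  # diverging coefficient or exploding SE marks separation
  sep <- !is.finite(co) | !is.finite(se) | abs(co) > 10 | se > 5

  rows <- list()
  for (v in names(dat)) {
    lev <- levels(dat[[v]])
    for (l in lev) {
      is_ref <- l == lev[1]
      term <- paste0(v, l)
      rows[[length(rows) + 1L]] <- if (is_ref) {
        tibble::tibble(variable = v, category = l, reference = TRUE,
                       or = 1, ci_low = NA_real_, ci_high = NA_real_,
                       log_or = 0, se = NA_real_, defined = TRUE)
      } else if (term %in% names(co) && !sep[[term]]) {
        tibble::tibble(variable = v, category = l, reference = FALSE,
                       or = exp(co[[term]]),
                       ci_low = exp(co[[term]] - z * se[[term]]),
                       ci_high = exp(co[[term]] + z * se[[term]]),
                       log_or = co[[term]], se = se[[term]], defined = TRUE)
      } else {
        tibble::tibble(variable = v, category = l, reference = FALSE,
                       or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                       log_or = NA_real_, se = NA_real_, defined = FALSE)
      }
    }
  }
  list(estimates = dplyr::bind_rows(rows), fit = fit,
       converged = fit$converged && sqrt(sum(grad^2)) < 1e-8,
       gradient_norm = sqrt(sum(grad^2)))
}

#' Association table: counts, crude and adjusted odds ratios per category
#'
#' For every covariate: category counts, cases with excessive intake, the
#' crude odds ratio against the variable's reference category with its Wald
#' 95% CI, and the adjusted odds ratio from a single joint logistic fit of
#' all covariates. Values are kept at full precision; round to 2 decimals
#' at render time.
#'
#' @param covariates Factor covariate table ([derive_covariates()] output).
#' @param outcome Logical excessive-intake flag per row.
#' @param continuity_correction Passed to [crude_or_ci()].
#' @param z Critical value.
#' @return Tibble: `variable`, `category`, `n_total`, `n_excessive`,
#'   `reference`, `crude_or`, `crude_ci_low`, `crude_ci_high`, `adj_or`,
#'   `adj_ci_low`, `adj_ci_high`, `crude_defined`, `adj_defined`.
#' @export
association_table <- function(covariates, outcome,
                              continuity_correction = FALSE, z = 1.959964) {
  dat <- dplyr::select(tibble::as_tibble(covariates),
                       -dplyr::any_of("child_id"))
  adj <- fit_excessive_model(dat, outcome, z = z)$estimates
  rows <- list()
  for (v in names(dat)) {
    lev <- levels(dat[[v]])
    n_tot <- tabulate(dat[[v]], nbins = length(lev))
    n_exc <- vapply(seq_along(lev),
                    function(i) sum(outcome[as.integer(dat[[v]]) == i]),
                    numeric(1))
    for (i in seq_along(lev)) {
      if (i == 1L) {
        cr <- list(or = 1, ci_low = NA_real_, ci_high = NA_real_, defined = TRUE)
      } else {
        cr <- crude_or_ci(n_ref = n_tot[1], x_ref = n_exc[1],
                          n_cmp = n_tot[i], x_cmp = n_exc[i], z = z,
                          continuity_correction = continuity_correction)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = v, category = lev[i],
        n_total = n_tot[i], n_excessive = n_exc[i], reference = i == 1L,
        crude_or = cr$or, crude_ci_low = cr$ci_low, crude_ci_high = cr$ci_high,
        crude_defined = cr$defined)
    }
  }
  tab <- dplyr::bind_rows(rows)
  dplyr::left_join(
    tab,
    dplyr::select(adj, "variable", "category", adj_or = "or",
                  adj_ci_low = "ci_low", adj_ci_high = "ci_high",
                  adj_defined = "defined"),
    by = c("variable", "category"))
}

#' Render an association table for printing
#'
#' Formats odds ratios and intervals to 2 decimals, reference rows as
#' `1.0 (ref)` and undefined estimates as an em-dash style `-`.
#'
#' @param tab Output of [association_table()].
#' @return Tibble of character columns ready for printing/writing.
#' @export
format_association_table <- function(tab) {
  fmt <- function(or, lo, hi, ref, defined) {
    dplyr::case_when(
      ref ~ "1.0 (ref)",
      !defined ~ "-",
      TRUE ~ sprintf("%.2f (%.2f, %.2f)", or, lo, hi))
  }
  tibble::tibble(
    variable = tab$variable, category = tab$category,
    n_total = tab$n_total, n_excessive = tab$n_excessive,
    crude = fmt(tab$crude_or, tab$crude_ci_low, tab$crude_ci_high,
                tab$reference, tab$crude_defined),
    adjusted = fmt(tab$adj_or, tab$adj_ci_low, tab$adj_ci_high,
                   tab$reference, tab$adj_defined))
}
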