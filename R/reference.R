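#' Published category counts and odds ratios of the motivating survey
#'
#' Category-level counts (total participants and participants with
#' excessive free sugar intake), crude odds ratios with 95% CIs, and
#' multivariable-adjusted odds ratios, as published for a survey of 332
#' Japanese children aged 3--6 years. These printed values are *inputs* to
#' this package: the synthetic-data generator uses the counts as covariate
#' marginals and the adjusted odds ratios as generating effects, and the
#' crude columns let the contingency arithmetic be recomputed from printed
#' counts alone.
#'
#' @return Tibble: `variable`, `category`, `n_total`, `n_excessive`,
#'   `reference` (logical), `crude_or`, `crude_ci_low`, `crude_ci_high`,
#'   `adj_or`, `adj_ci_low`, `adj_ci_high`. The undefined (zero-event)
#'   category carries `NA` odds ratios.
#' @export
reference_cohort_counts <- function() {
  path <- system.file("extdata", "cohort_reference_counts.csv",
                      package = "freesugar", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    variable = readr::col_character(),
                    category = readr::col_character(),
                    n_total = readr::col_integer(),
                    n_excessive = readr::col_integer(),
                    reference = readr::col_logical(),
                    .default = readr::col_double()))
}
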