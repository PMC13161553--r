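#' Calculated energy of mixed diets from ingredient values
#'
#' Under the additivity assumption, the energy of a mixed diet is the
#' DM-inclusion-weighted sum of its ingredients' energies:
#' `sum(inclusion_i / 100 * value_i)`, with energy-free supplements
#' (minerals, salt, premix) contributing zero. Every energetic component
#' must have a value; missing ingredients raise an error naming them.
#'
#' @param formulations Long-format diet formulations (see
#'   [validate_formulations()]).
#' @param values A data frame with an `ingredient_id` column and one or
#'   more numeric value columns (e.g. `ge`, `ivde`, `de`, `me`, all
#'   kcal/kg DM).
#' @param value_cols Which value columns to sum; default every numeric
#'   column of `values`.
#' @return One row per diet with a weighted-sum column for each value
#'   column.
#' @examples
#' calculated_diet_energy(
#'   load_feed_table("validation_diets"),
#'   load_feed_table("ingredient_energy"),
#'   value_cols = c("de", "me")
#' )
#' @export
calculated_diet_energy <- function(formulations, values, value_cols = NULL) {
  comp <- .energetic_components(formulations)
  values <- as_tibble(values)
  if (!"ingredient_id" %in% names(values)) {
    abort("`values` must have an `ingredient_id` column.",
      class = c("feedenergy_error_schema", "feedenergy_error"))
  }
  if (is.null(value_cols)) {
    value_cols <- names(values)[vapply(values, is.numeric, logical(1))]
  }
  missing_cols <- setdiff(value_cols, names(values))
  if (length(missing_cols) > 0) {
    abort(sprintf("Value column(s) not found: %s",
      paste(missing_cols, collapse = ", ")),
      class = c("feedenergy_error_schema", "feedenergy_error"))
  }
  gap <- setdiff(unique(comp$ingredient_id), values$ingredient_id)
  if (length(gap) > 0) {
    abort(
      sprintf("No ingredient value supplied for: %s",
        paste(gap, collapse = ", ")),
      class = c("feedenergy_error_named_gap", "feedenergy_error")
    )
  }
  comp %>%
    left_join(select(values, "ingredient_id", all_of(value_cols)),
      by = "ingredient_id") %>%
    group_by(.data$diet_id) %>%
    summarise(across(all_of(value_cols),
      ~ sum(.data$inclusion / 100 * .x)), .groups = "drop")
}

#' Predicted energy of mixed diets via a calibration
#'
#' Ingredient-level energies are first predicted from their IVDE through a
#' fitted calibration, then combined by the same DM-inclusion-weighted sum
#' as [calculated_diet_energy()]. With an identity calibration (slope 1,
#' intercept 0) this reduces to the weighted sum of the IVDE values
#' themselves.
#'
#' @inheritParams calculated_diet_energy
#' @param model A `feed_calibration` object.
#' @param ingredient_ivde Data frame with `ingredient_id` and `ivde`
#'   columns (kcal/kg DM).
#' @return One row per diet: `diet_id`, `predicted` (kcal/kg DM).
#' @examples
#' panel <- load_feed_table("ingredient_energy")
#' model <- fit_calibration(panel, "de")
#' predicted_diet_energy(load_feed_table("validation_diets"), model, panel)
#' @export
predicted_diet_energy <- function(formulations, model, ingredient_ivde) {
  stopifnot(inherits(model, "feed_calibration"))
  ingredient_ivde <- as_tibble(ingredient_ivde)
  pred <- ingredient_ivde %>%
    transmute(.data$ingredient_id,
      predicted = model$slope * .data$ivde + model$intercept)
  calculated_diet_energy(formulations, pred, value_cols = "predicted")
}

#' Average relative difference (ARD)
#'
#' Root-mean-square difference between determined and predicted values,
#' relative to the mean of the determined values:
#' `ARD = 100 * sqrt(mean((determined - predicted)^2)) / mean(determined)` (%).
#' It is zero iff the vectors are equal and invariant to a common scaling
#' of both.
#'
#' @param determined,predicted Numeric vectors of equal length.
#' @return The ARD in percent (scalar).
#' @examples
#' t7 <- dplyr::filter(load_feed_table("prediction"), quantity == "de")
#' ard(t7$determined, t7$predicted)
#' @export
ard <- function(determined, predicted) {
  if (length(determined) != length(predicted) || length(determined) < 1) {
    abort("`determined` and `predicted` must be non-empty and equal length.",
      class = c("feedenergy_error_schema", "feedenergy_error"))
  }
  m <- mean(determined)
  if (!is.finite(m) || m <= 0) {
    abort("ARD undefined: mean of determined values must be positive.",
      class = c("feedenergy_error_undefined_statistic", "feedenergy_error"))
  }
  100 * sqrt(mean((determined - predicted)^2)) / m
}

#' One-sample t-test of replicate determinations against a reference
#'
#' Tests whether replicate determined values differ from a fixed reference
#' (e.g. a diet's predicted energy): `t = (mean(x) - reference) / sem`,
#' `df = n - 1`, two-sided. With zero replicate variance and a non-zero
#' difference the p-value is reported at the machine floor with a warning.
#'
#' @param x Numeric vector of replicate determinations (length >= 2).
#' @param reference Reference value.
#' @return A one-row tibble: `n`, `mean`, `mean_diff`, `sem`, `statistic`,
#'   `df`, `p_value`.
#' @examples
#' one_sample_t(c(3960, 3975, 3990, 3981, 3970, 3980), reference = 3980)
#' @export
one_sample_t <- function(x, reference) {
  if (length(x) < 2) {
    abort("At least 2 replicates are required for a one-sample t-test.",
      class = c("feedenergy_error_schema", "feedenergy_error"))
  }
  n <- length(x)
  sem <- sd(x) / sqrt(n)
  diff <- mean(x) - reference
  if (sem == 0) {
    if (diff != 0) {
      warn("Zero replicate variance with a non-zero difference; p-value at machine floor.",
        class = "feedenergy_warning_zero_variance")
      p <- .Machine$double.xmin
      stat <- sign(diff) * Inf
    } else {
      p <- 1
      stat <- 0
    }
  } else {
    stat <- diff / sem
    p <- 2 * pt(abs(stat), df = n - 1, lower.tail = FALSE)
  }
  tibble(n = n, mean = mean(x), mean_diff = diff, sem = sem,
    statistic = stat, df = n - 1, p_value = p)
}

#' @describeIn one_sample_t Recover the test from a printed summary
#'   (mean difference, SEM and replicate count) when raw replicates are
#'   unavailable. Vectorized.
#' @param mean_diff Mean determined-minus-reference difference(s).
#' @param sem Standard error(s) of the mean.
#' @param n Replicate count(s).
#' @export
one_sample_t_summary <- function(mean_diff, sem, n) {
  stat <- mean_diff / sem
  tibble(
    mean_diff = mean_diff, sem = sem, n = n,
    statistic = stat, df = n - 1,
    p_value = 2 * pt(abs(stat), df = n - 1, lower.tail = FALSE)
  )
}

#' Agreement regression of comparator on determined values
#'
#' Additivity (or prediction accuracy) across a panel of diets is judged
#' by regressing the calculated or predicted values on the determined
#' values and testing the line against the identity: slope against 1 and
#' intercept against 0 ([test_coefficients()]). When neither test is
#' significant at `alpha` the panel is declared `"additive"` — the
#' comparator tracks the determined energies without systematic bias.
#'
#' @param determined,comparator Numeric vectors (length >= 3).
#' @param alpha Significance level for the verdict.
#' @return An object of class `feed_agreement`: a list with the
#'   `feed_calibration` `model`, the coefficient `tests` tibble,
#'   `p_slope`, `p_intercept` and the `verdict` string (`"additive"` or
#'   `"non-additive"`).
#' @examples
#' t6 <- dplyr::filter(load_feed_table("agreement"), quantity == "de")
#' agreement_regression(t6$determined, t6$calculated)
#' @export
agreement_regression <- function(determined, comparator, alpha = 0.05) {
  pairs <- tibble(determined = determined, comparator = comparator)
  model <- fit_calibration(pairs, response = "comparator",
    predictor = "determined")
  tests <- test_coefficients(model, slope = 1, intercept = 0)
  p_slope <- tests$p_value[tests$term == "slope"]
  p_intercept <- tests$p_value[tests$term == "intercept"]
  verdict <- if (p_slope > alpha && p_intercept > alpha) {
    "additive"
  } else {
    "non-additive"
  }
  structure(
    list(model = model, tests = tests, p_slope = p_slope,
      p_intercept = p_intercept, alpha = alpha, verdict = verdict),
    class = "feed_agreement"
  )
}

#' @export
print.feed_agreement <- function(x, ...) {
  cat(sprintf(
    "<feed_agreement> slope %.3f (p vs 1: %.3f), intercept %.0f (p vs 0: %.3f) -> %s\n",
    x$model$slope, x$p_slope, x$model$intercept, x$p_intercept, x$verdict
  ))
  invisible(x)
}

#' @rdname tidy.feed_calibration
#' @method tidy feed_agreement
#' @export
tidy.feed_agreement <- function(x, ...) {
  x$tests
}

#' @rdname tidy.feed_calibration
#' @method glance feed_agreement
#' @export
glance.feed_agreement <- function(x, ...) {
  glance(x$model) %>%
    mutate(p_slope = x$p_slope, p_intercept = x$p_intercept,
      verdict = x$verdict)
}
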