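#' Fit a linear energy calibration
#'
#' Ordinary least-squares calibration of an in vivo energy value (DE or
#' ME, kcal/kg DM) on the in vitro digestible energy (IVDE) of the same
#' samples. The fitted object stores, besides the [stats::lm()] fit, the
#' quantities needed to reconstruct mean-response confidence intervals by
#' hand: sample size `n`, predictor mean `x_mean`, corrected sum of
#' squares `s_xx`, residual standard deviation
#' `rsd = sqrt(SSE / (n - 2))` and `r2 = 1 - SSE/SST`.
#'
#' @param data A data frame holding the calibration pairs.
#' @param response Name of the response column (`"de"` or `"me"` for the
#'   reference panel, but any numeric column works).
#' @param predictor Name of the predictor column (default `"ivde"`).
#' @return An object of class `feed_calibration` with components
#'   `response`, `predictor`, `slope`, `intercept`, `n`, `r2`, `rsd`,
#'   `x_mean`, `s_xx`, `df_resid`, `fit` (the underlying `lm`) and `data`
#'   (the pairs used, columns `x` and `y`). Supports [tidy()], [glance()],
#'   [predict()][predict.feed_calibration] and [autoplot()].
#' @examples
#' panel <- load_feed_table("ingredient_energy")
#' fit_calibration(panel, response = "de")
#' @export
fit_calibration <- function(data, response = "de", predictor = "ivde") {
  data <- as_tibble(data)
  response <- match.arg(response, choices = names(data))
  predictor <- match.arg(predictor, choices = names(data))
  pairs <- tibble(x = as.numeric(data[[predictor]]),
    y = as.numeric(data[[response]]))
  pairs <- pairs %>% filter(!is.na(.data$x), !is.na(.data$y))
  n <- nrow(pairs)
  if (n < 3) {
    abort(sprintf(
      "At least 3 complete pairs are required to calibrate (got %d): the residual degrees of freedom n - 2 must be positive.",
      n
    ), class = c("feedenergy_error_degenerate_fit", "feedenergy_error"))
  }
  s_xx <- sum((pairs$x - mean(pairs$x))^2)
  if (s_xx <= 0) {
    abort("Predictor is constant; the calibration is degenerate.",
      class = c("feedenergy_error_degenerate_fit", "feedenergy_error"))
  }
  fit <- lm(y ~ x, data = pairs)
  sse <- sum(fit$residuals^2)
  sst <- sum((pairs$y - mean(pairs$y))^2)
  structure(
    list(
      response = response,
      predictor = predictor,
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      n = n,
      r2 = 1 - sse / sst,
      rsd = sqrt(sse / (n - 2)),
      x_mean = mean(pairs$x),
      s_xx = s_xx,
      df_resid = n - 2L,
      fit = fit,
      data = pairs
    ),
    class = "feed_calibration"
  )
}

#' Predict mean response with a confidence interval
#'
#' Point prediction `slope * x0 + intercept` with the confidence interval
#' of the *mean response* at `x0`:
#' `half-width = t(1 - alpha/2, n - 2) * rsd * sqrt(1/n + (x0 - x_mean)^2 / s_xx)`.
#' This is the interval for the expected energy of samples at that IVDE,
#' not a prediction interval for a single new sample; the half-width is
#' smallest at `x0 = x_mean` and grows with leverage.
#'
#' @param model A `feed_calibration` object.
#' @param x0 Numeric vector of predictor values.
#' @param level Confidence level (default 0.95).
#' @return A tibble with columns `x`, `estimate`, `lower`, `upper`.
#' @examples
#' model <- fit_calibration(load_feed_table("ingredient_energy"), "de")
#' predict_with_ci(model, c(3969, 1910))
#' @export
predict_with_ci <- function(model, x0, level = 0.95) {
  stopifnot(inherits(model, "feed_calibration"))
  if (model$df_resid < 1) {
    abort("No residual degrees of freedom: cannot form a confidence interval.",
      class = c("feedenergy_error_no_interval", "feedenergy_error"))
  }
  est <- model$slope * x0 + model$intercept
  half <- qt(1 - (1 - level) / 2, df = model$df_resid) * model$rsd *
    sqrt(1 / model$n + (x0 - model$x_mean)^2 / model$s_xx)
  tibble(x = x0, estimate = est, lower = est - half, upper = est + half)
}

#' @rdname predict_with_ci
#' @param object A `feed_calibration` object.
#' @param ... Unused.
#' @export
predict.feed_calibration <- function(object, x0, level = 0.95, ...) {
  predict_with_ci(object, x0, level = level)
}

#' Test calibration coefficients against reference values
#'
#' Two-sided t-tests of the fitted slope and intercept against null values
#' (by default the identity line: slope 1, intercept 0), using the OLS
#' standard errors on `n - 2` degrees of freedom. A calibration whose
#' coefficients are indistinguishable from the identity maps the in vitro
#' assay onto the in vivo scale without systematic bias.
#'
#' @param model A `feed_calibration` object.
#' @param slope,intercept Null values to test against.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std_error`, `null_value`, `statistic`, `p_value`.
#' @examples
#' model <- fit_calibration(load_feed_table("ingredient_energy"), "de")
#' test_coefficients(model)
#' @export
test_coefficients <- function(model, slope = 1, intercept = 0) {
  stopifnot(inherits(model, "feed_calibration"))
  # the near-zero-residual case is handled explicitly below, so the
  # "essentially perfect fit" notice from summary.lm is redundant here
  s <- withCallingHandlers(
    summary(model$fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  est <- s[, "Estimate"]
  se <- s[, "Std. Error"]
  null <- c(intercept, slope)
  stat <- (est - null) / se
  # an (essentially) zero-residual fit has vanishing standard errors; the
  # test is then decided by whether the estimate equals the null value
  yscale <- mean(abs(model$data$y)) + 1
  if (model$rsd <= 1e-8 * yscale) {
    stat <- ifelse(abs(est - null) <= 1e-6 * pmax(abs(null), 1), 0, Inf)
  }
  tibble(
    term = c("intercept", "slope"),
    estimate = unname(est),
    std_error = unname(se),
    null_value = null,
    statistic = unname(stat),
    p_value = unname(2 * pt(abs(stat), df = model$df_resid, lower.tail = FALSE))
  )
}

#' Compare two calibrations
#'
#' Tests whether two calibrations share a slope and an intercept by
#' pooling their stored pairs into one OLS fit with a group indicator and
#' its interaction with the predictor (`y ~ x * group`): the interaction
#' p-value tests slope equality, the group main-effect p-value intercept
#' equality.
#'
#' @param model_a,model_b `feed_calibration` objects.
#' @return A tibble with `p_slope` and `p_intercept` plus the estimated
#'   slope/intercept differences (`b` minus `a`).
#' @examples
#' panel <- load_feed_table("ingredient_energy")
#' compare_calibrations(
#'   fit_calibration(panel, "de"),
#'   fit_calibration(panel, "me")
#' )
#' @export
compare_calibrations <- function(model_a, model_b) {
  stopifnot(inherits(model_a, "feed_calibration"),
    inherits(model_b, "feed_calibration"))
  ra <- range(model_a$data$x)
  rb <- range(model_b$data$x)
  if (ra[2] < rb[1] || rb[2] < ra[1]) {
    warn("The two calibrations were fitted on non-overlapping predictor ranges; the comparison extrapolates.",
      class = "feedenergy_warning_support_mismatch")
  }
  pooled <- bind_rows(
    model_a$data %>% mutate(group = 0),
    model_b$data %>% mutate(group = 1)
  )
  fit <- lm(y ~ x * group, data = pooled)
  s <- summary(fit)$coefficients
  tibble(
    slope_diff = unname(s["x:group", "Estimate"]),
    p_slope = unname(s["x:group", "Pr(>|t|)"]),
    intercept_diff = unname(s["group", "Estimate"]),
    p_intercept = unname(s["group", "Pr(>|t|)"])
  )
}

#' Pearson correlation between two energy measures
#'
#' @param data A data frame.
#' @param x,y Column names of the two measures.
#' @return A tibble with `n`, `r` and the two-sided `p_value`. The squared
#'   `r` equals the R-squared of the simple regression of `y` on `x`.
#' @examples
#' energy_correlation(load_feed_table("ingredient_energy"), "ivde", "de")
#' @export
energy_correlation <- function(data, x, y) {
  data <- as_tibble(data)
  xv <- as.numeric(data[[x]])
  yv <- as.numeric(data[[y]])
  ok <- !is.na(xv) & !is.na(yv)
  xv <- xv[ok]
  yv <- yv[ok]
  if (length(xv) < 3) {
    abort("At least 3 complete pairs are required.",
      class = c("feedenergy_error_degenerate_fit", "feedenergy_error"))
  }
  if (var(xv) == 0 || var(yv) == 0) {
    abort("Correlation undefined for constant input.",
      class = c("feedenergy_error_undefined_correlation", "feedenergy_error"))
  }
  ct <- cor.test(xv, yv)
  tibble(n = length(xv), r = unname(ct$estimate), p_value = ct$p.value)
}

#' @export
print.feed_calibration <- function(x, ...) {
  cat(sprintf(
    "<feed_calibration> %s = %.3f x %s %s %.0f  (n = %d, R2 = %.2f, RSD = %.0f kcal/kg DM)\n",
    x$response, x$slope, x$predictor,
    ifelse(x$intercept < 0, "-", "+"), abs(x$intercept),
    x$n, x$r2, x$rsd
  ))
  invisible(x)
}

#' Tidy and glance methods for calibrations
#'
#' Broom-style accessors: `tidy()` returns the coefficient table,
#' `glance()` a one-row model summary.
#'
#' @param x,object A `feed_calibration` object.
#' @param ... Unused.
#' @return A tibble.
#' @examples
#' model <- fit_calibration(load_feed_table("ingredient_energy"), "de")
#' tidy(model)
#' glance(model)
#' @method tidy feed_calibration
#' @export
tidy.feed_calibration <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = unname(s[, "Estimate"]),
    std_error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p_value = unname(s[, "Pr(>|t|)"])
  )
}

#' @rdname tidy.feed_calibration
#' @method glance feed_calibration
#' @export
glance.feed_calibration <- function(x, ...) {
  tibble(
    response = x$response,
    slope = x$slope,
    intercept = x$intercept,
    n = x$n,
    r2 = x$r2,
    rsd = x$rsd,
    df_resid = x$df_resid
  )
}

#' Plot a calibration with its mean-response confidence band
#'
#' Scatter of the calibration pairs, the fitted line and the pointwise
#' confidence band of the mean response.
#'
#' @param object A `feed_calibration` object.
#' @param level Confidence level for the band.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(fit_calibration(load_feed_table("ingredient_energy"), "de"))
#' @method autoplot feed_calibration
#' @export
autoplot.feed_calibration <- function(object, level = 0.95, ...) {
  grid <- tibble(x = seq(min(object$data$x), max(object$data$x),
    length.out = 100))
  band <- predict_with_ci(object, grid$x, level = level)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$x, ymin = .data$lower, ymax = .data$upper),
      inherit.aes = FALSE, alpha = 0.2
    ) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("%s (kcal/kg DM)", toupper(object$predictor)),
      y = sprintf("%s (kcal/kg DM)", toupper(object$response)),
      title = sprintf(
        "%s = %.3f × %s %s %.0f   (R² = %.2f, RSD = %.0f)",
        toupper(object$response), object$slope, toupper(object$predictor),
        ifelse(object$intercept < 0, "−", "+"), abs(object$intercept),
        object$r2, object$rsd
      )
    ) +
    ggplot2::theme_minimal()
}
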