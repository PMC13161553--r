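#' Diet-level energy from balance records
#'
#' Computes, for every balance observation, the gross, digestible and
#' metabolizable energy concentration of the diet on a DM basis:
#' `ge_d = gei / dmi`, `de_d = (gei - geo) / dmi`,
#' `me_d = (gei - geo - geu) / dmi`, together with the digestibility
#' coefficient `d_coef = de_d / ge_d` and metabolizability
#' `m_coef = me_d / ge_d`. The balance invariants guarantee
#' `me_d <= de_d <= ge_d`.
#'
#' @param obs A tibble of balance observations (see [validate_balance()]).
#' @return The input with columns `ge_d`, `de_d`, `me_d` (kcal/kg DM),
#'   `d_coef` and `m_coef` appended.
#' @examples
#' obs <- load_feed_table("balance")
#' diet_energy(obs)
#' @seealso [aggregate_diet_energy()] for per-diet summaries.
#' @export
diet_energy <- function(obs) {
  obs <- as_tibble(obs)
  validate_balance(obs)
  obs %>%
    mutate(
      ge_d = .data$gei / .data$dmi,
      de_d = (.data$gei - .data$geo) / .data$dmi,
      me_d = (.data$gei - .data$geo - .data$geu) / .data$dmi,
      d_coef = .data$de_d / .data$ge_d,
      m_coef = .data$me_d / .data$ge_d
    )
}

#' Flag outliers with the interquartile-range rule
#'
#' Values outside `[Q1 - k * IQR, Q3 + k * IQR]` are flagged. Quartiles are
#' the Tukey hinges ([stats::fivenum()]): the medians of the lower and upper
#' halves of the sorted data, each half including the overall median when
#' `length(x)` is odd. The convention is fixed so that screening decisions
#' are reproducible; ties pose no ambiguity because hinges are order
#' statistics (or midpoints of two of them).
#'
#' With fewer than `min_n` values the screen is skipped with a warning and
#' everything is kept.
#'
#' @param x Numeric vector.
#' @param k Whisker multiplier (1.5 by convention).
#' @param min_n Minimum number of values required to screen.
#' @return A list with `kept` and `flagged` (the values), `keep` (logical
#'   index aligned with `x`) and `bounds` (the screening interval).
#' @examples
#' iqr_screen(c(10, 12, 11, 13, 12, 30))
#' @export
iqr_screen <- function(x, k = 1.5, min_n = 4) {
  stopifnot(is.numeric(x))
  if (length(x) < min_n) {
    warn(sprintf(
      "IQR screen skipped: %d value(s) supplied, %d required.",
      length(x), min_n
    ), class = "feedenergy_warning_screen_skipped")
    return(list(kept = x, flagged = numeric(0),
      keep = rep(TRUE, length(x)), bounds = c(-Inf, Inf)))
  }
  h <- fivenum(x)
  q1 <- h[2]
  q3 <- h[4]
  iqr <- q3 - q1
  bounds <- c(q1 - k * iqr, q3 + k * iqr)
  keep <- x >= bounds[1] & x <= bounds[2]
  list(kept = x[keep], flagged = x[!keep], keep = keep, bounds = bounds)
}

#' Aggregate balance observations to per-diet energy
#'
#' Per-observation energies are computed first ([diet_energy()]) and then
#' averaged within diet, the order the replicated trial is summarised in
#' the field. Optionally, observations whose `de_d` falls outside the
#' interquartile screen ([iqr_screen()]) within their diet are dropped
#' before averaging. Replicate CVs are `100 * sd / mean`.
#'
#' @param obs A tibble of balance observations.
#' @param screen Apply the IQR outlier screen within each diet (default
#'   `TRUE`; diets with fewer than four observations are never screened).
#' @return One row per diet: `diet_id`, `n_obs`, `ge_d`, `de_d`, `me_d`,
#'   `d_coef`, `m_coef`, `cv_de`, `cv_me`. Coefficients are ratios of the
#'   mean energies. CVs are `NA` for single-observation diets.
#' @examples
#' aggregate_diet_energy(load_feed_table("balance"))
#' @export
aggregate_diet_energy <- function(obs, screen = TRUE) {
  per_obs <- diet_energy(obs)
  if (nrow(per_obs) == 0) {
    abort("No balance observations supplied.",
      class = c("feedenergy_error_missing_diet", "feedenergy_error"))
  }
  if (screen) {
    per_obs <- per_obs %>%
      group_by(.data$diet_id) %>%
      filter(if (dplyr::n() >= 4) iqr_screen(.data$de_d)$keep else TRUE) %>%
      ungroup()
  }
  per_obs %>%
    group_by(.data$diet_id) %>%
    summarise(
      n_obs = dplyr::n(),
      cv_de = 100 * sd(.data$de_d) / mean(.data$de_d),
      cv_me = 100 * sd(.data$me_d) / mean(.data$me_d),
      ge_d = mean(.data$ge_d),
      de_d = mean(.data$de_d),
      me_d = mean(.data$me_d),
      .groups = "drop"
    ) %>%
    mutate(d_coef = .data$de_d / .data$ge_d, m_coef = .data$me_d / .data$ge_d) %>%
    select("diet_id", "n_obs", "ge_d", "de_d", "me_d",
      "d_coef", "m_coef", "cv_de", "cv_me")
}

# energetic (non-supplement) components of each diet
.energetic_components <- function(formulations) {
  validate_formulations(formulations)
  as_tibble(formulations) %>% filter(!.data$energy_free)
}

#' Ingredient energy by the direct method
#'
#' For diets consisting almost entirely of one test ingredient (cereal
#' grains fed near-sole), the ingredient energy is the diet digestibility
#' scaled to the ingredient's gross energy:
#' `de_ti = ge_ti * de_d / ge_d` and `me_ti = ge_ti * me_d / ge_d`.
#'
#' @param diets Per-diet energies from [aggregate_diet_energy()].
#' @param formulations Long-format diet formulations.
#' @param ingredients Ingredient composition table (for `ge`).
#' @param diet_ids Diets to evaluate; default all diets in `diets`.
#' @param min_inclusion Minimum test-ingredient inclusion (% of diet DM)
#'   for the direct method to be valid; below it an error directs to the
#'   substitution method.
#' @return One row per diet: `ingredient_id`, `diet_id`, `method`,
#'   `p_ti` (`NA` for direct), `de`, `me` (kcal/kg DM), plus replicate
#'   bookkeeping (`n_obs`, `cv_de`, `cv_me`) carried from `diets`.
#' @examples
#' diets <- aggregate_diet_energy(load_feed_table("balance"))
#' direct_ingredient_energy(
#'   diets, load_feed_table("experimental_diets"),
#'   load_feed_table("ingredients"),
#'   diet_ids = paste0("d", 1:6)
#' )
#' @export
direct_ingredient_energy <- function(diets, formulations, ingredients,
                                     diet_ids = NULL, min_inclusion = 90) {
  validate_ingredients(ingredients)
  comp <- .energetic_components(formulations)
  if (is.null(diet_ids)) diet_ids <- diets$diet_id
  test <- comp %>%
    filter(.data$diet_id %in% diet_ids) %>%
    group_by(.data$diet_id) %>%
    slice_max(.data$inclusion, n = 1, with_ties = FALSE) %>%
    ungroup()
  low <- test %>% filter(.data$inclusion < min_inclusion)
  if (nrow(low) > 0) {
    abort(
      sprintf(
        paste0(
          "Direct method requires a test-ingredient inclusion >= %s%%; ",
          "diet(s) %s fall short. Use substitution_ingredient_energy()."
        ),
        format(min_inclusion), paste(low$diet_id, collapse = ", ")
      ),
      class = c("feedenergy_error_wrong_method", "feedenergy_error")
    )
  }
  test %>%
    inner_join(diets, by = "diet_id") %>%
    left_join(select(as_tibble(ingredients), "ingredient_id", ge_ti = "ge"),
      by = "ingredient_id") %>%
    transmute(
      ingredient_id = .data$ingredient_id,
      diet_id = .data$diet_id,
      method = "direct",
      p_ti = NA_real_,
      de = .data$ge_ti * .data$d_coef,
      me = .data$ge_ti * .data$m_coef,
      n_obs = .data$n_obs,
      cv_de = .data$cv_de,
      cv_me = .data$cv_me
    )
}

#' Ingredient energy by the substitution (difference) method
#'
#' For ingredients that cannot be fed near-sole, a test diet replaces part
#' of a basal diet with the test ingredient. The ingredient digestibility
#' coefficient is recovered from the displacement it induces:
#' `d_ti = d_cd + (d_td - d_cd) / p_ti`, applied separately to the
#' digestibility (`d_coef`) and metabolizability (`m_coef`) coefficients of
#' the basal (`cd`) and test (`td`) diets, with energies
#' `de_ti = ge_ti * d_ti` (and analogously for ME). `p_ti` is the share of
#' the test diet's gross energy contributed by the test ingredient,
#' `p_ti = (inclusion/100) * ge_ti / ge_d`, with `ge_d` the analyzed test
#' diet GE (here `gei/dmi` from the balance records, which equals the
#' analyzed GE by construction).
#'
#' The test ingredient of each diet is the energetic component that is not
#' the basal ingredient; exactly one such component must be present.
#'
#' @inheritParams direct_ingredient_energy
#' @param basal_diet `diet_id` of the basal diet supplying `d_cd`/`m_cd`.
#' @param diet_ids Test diets to evaluate; default all diets in `diets`
#'   other than `basal_diet`.
#' @return One row per test diet, same shape as
#'   [direct_ingredient_energy()] with `method = "substitution"` and the
#'   energy proportion `p_ti` recorded.
#' @examples
#' diets <- aggregate_diet_energy(load_feed_table("balance"))
#' substitution_ingredient_energy(
#'   diets, load_feed_table("experimental_diets"),
#'   load_feed_table("ingredients"),
#'   basal_diet = "d1", diet_ids = "d20"
#' )
#' @export
substitution_ingredient_energy <- function(diets, formulations, ingredients,
                                           basal_diet = "d1", diet_ids = NULL) {
  validate_ingredients(ingredients)
  comp <- .energetic_components(formulations)
  basal <- diets %>% filter(.data$diet_id == basal_diet)
  if (nrow(basal) != 1) {
    abort(
      sprintf("Basal diet '%s' not found (or not unique) in `diets`.", basal_diet),
      class = c("feedenergy_error_configuration", "feedenergy_error")
    )
  }
  basal_ingredient <- comp %>%
    filter(.data$diet_id == basal_diet) %>%
    slice_max(.data$inclusion, n = 1, with_ties = FALSE) %>%
    pull("ingredient_id")
  if (is.null(diet_ids)) diet_ids <- setdiff(diets$diet_id, basal_diet)
  test <- comp %>%
    filter(.data$diet_id %in% diet_ids,
      .data$ingredient_id != basal_ingredient)
  n_test <- test %>% count(.data$diet_id)
  bad <- n_test %>% filter(.data$n != 1)
  if (nrow(bad) > 0 || !setequal(n_test$diet_id, diet_ids)) {
    abort(
      "Each substitution diet must contain exactly one non-basal energetic component.",
      class = c("feedenergy_error_configuration", "feedenergy_error")
    )
  }
  out <- test %>%
    inner_join(diets, by = "diet_id") %>%
    left_join(select(as_tibble(ingredients), "ingredient_id", ge_ti = "ge"),
      by = "ingredient_id") %>%
    mutate(p_ti = (.data$inclusion / 100) * .data$ge_ti / .data$ge_d)
  if (any(out$p_ti <= 0 | out$p_ti > 1)) {
    bad <- out$diet_id[out$p_ti <= 0 | out$p_ti > 1]
    abort(
      sprintf("Energy proportion p_ti outside (0, 1] for diet(s): %s",
        paste(bad, collapse = ", ")),
      class = c("feedenergy_error_invalid_proportion", "feedenergy_error")
    )
  }
  out %>%
    transmute(
      ingredient_id = .data$ingredient_id,
      diet_id = .data$diet_id,
      method = "substitution",
      p_ti = .data$p_ti,
      de = .data$ge_ti * (basal$d_coef + (.data$d_coef - basal$d_coef) / .data$p_ti),
      me = .data$ge_ti * (basal$m_coef + (.data$m_coef - basal$m_coef) / .data$p_ti),
      n_obs = .data$n_obs,
      cv_de = .data$cv_de,
      cv_me = .data$cv_me
    )
}

#' Ingredient energies for a whole trial
#'
#' Dispatches each diet to the direct or the substitution method: diets
#' whose single energetic component reaches `min_inclusion` (and the basal
#' diet itself) are treated as direct; all others as substitution diets
#' against `basal_diet`.
#'
#' @inheritParams substitution_ingredient_energy
#' @param min_inclusion Direct-method inclusion threshold (% of diet DM).
#' @return One row per diet with the evaluated ingredient, bound from both
#'   methods.
#' @examples
#' diets <- aggregate_diet_energy(load_feed_table("balance"))
#' ingredient_energies(
#'   diets, load_feed_table("experimental_diets"),
#'   load_feed_table("ingredients"),
#'   diet_ids = paste0("d", 1:20)
#' )
#' @export
ingredient_energies <- function(diets, formulations, ingredients,
                                basal_diet = "d1", diet_ids = NULL,
                                min_inclusion = 90) {
  comp <- .energetic_components(formulations)
  if (is.null(diet_ids)) diet_ids <- intersect(diets$diet_id, comp$diet_id)
  top <- comp %>%
    filter(.data$diet_id %in% diet_ids) %>%
    group_by(.data$diet_id) %>%
    summarise(max_incl = max(.data$inclusion), n_energetic = dplyr::n(),
      .groups = "drop")
  direct_ids <- top %>%
    filter(.data$n_energetic == 1, .data$max_incl >= min_inclusion) %>%
    pull("diet_id")
  direct_ids <- union(direct_ids, intersect(basal_diet, diet_ids))
  subst_ids <- setdiff(diet_ids, direct_ids)
  res <- list()
  if (length(direct_ids) > 0) {
    res$direct <- direct_ingredient_energy(diets, formulations, ingredients,
      diet_ids = direct_ids, min_inclusion = min_inclusion)
  }
  if (length(subst_ids) > 0) {
    res$subst <- substitution_ingredient_energy(diets, formulations,
      ingredients, basal_diet = basal_diet, diet_ids = subst_ids)
  }
  bind_rows(res) %>% arrange(match(.data$diet_id, diet_ids))
}
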