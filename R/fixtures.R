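#' Load a packaged reference table
#'
#' The package ships plain-text transcriptions of the printed tables of a
#' growing-pig energy evaluation study of 20 feed ingredients: ingredient
#' chemical composition, the formulations and analyzed composition of 20
#' experimental and 10 validation diets, per-diet energy balance summaries,
#' the in vitro / in vivo ingredient energy panel, and the two validation
#' comparisons (determined vs. calculated, determined vs. predicted).
#'
#' Canonical names (printed-table aliases in parentheses):
#'
#' * `"ingredients"` (`"table1"`) — ingredient chemical composition.
#' * `"experimental_diets"` (`"table2"`) — long-format formulations of the
#'   20 single-test-ingredient diets `d1`–`d20`.
#' * `"validation_diets"` (`"table3"`) — formulations of the 10 mixed
#'   validation diets `v1`–`v10`.
#' * `"diet_composition"` — analyzed chemistry (DM, GE, CP, ash, NDF, ADF)
#'   of all 30 diets.
#' * `"balance"` (`"table4"`) — per-diet energy balance rows. The source
#'   table prints diet means, not per-pig records; each row is loaded as a
#'   single pseudo-observation (`pig_id` prefixed `"diet-mean-"`), so
#'   replicate counts and CVs are not recoverable from this fixture.
#' * `"ingredient_energy"` (`"table5"`) — IVDE, in vivo DE and ME with
#'   replicate CVs, IVDE:DE and IVDE:ME ratios, and calibration-predicted
#'   values with 95% confidence limits for the 20 ingredients.
#' * `"agreement"` (`"table6"`) — determined vs. calculated GE/IVDE/DE/ME
#'   of the validation diets, long format.
#' * `"prediction"` (`"table7"`) — determined vs. predicted DE/ME with the
#'   replicate SEM and printed p-value label; a numeric `p_value` column is
#'   derived from the label (censored entries such as `"<0.001"` parse to
#'   their bound).
#'
#' Every load re-checks the file's MD5 checksum against the value recorded
#' at packaging time and re-validates the record invariants, so a corrupted
#' installation fails loudly rather than silently.
#'
#' @param name Table name or alias (see above).
#' @return A tibble of typed, invariant-checked records. The source table
#'   is recorded in the `"provenance"` attribute.
#' @examples
#' load_feed_table("ingredients")
#' load_feed_table("table5")
#' @export
load_feed_table <- function(name) {
  if (length(name) != 1 || !is.character(name) || is.na(name) || !nzchar(name)) {
    abort("`name` must be a single non-empty table name.",
      class = c("feedenergy_error_usage", "feedenergy_error"))
  }
  aliases <- c(
    table1 = "ingredients", table2 = "experimental_diets",
    table3 = "validation_diets", table4 = "balance",
    table5 = "ingredient_energy", table6 = "agreement",
    table7 = "prediction"
  )
  if (name %in% names(aliases)) name <- aliases[[name]]
  info <- .fixture_registry[[name]]
  if (is.null(info)) {
    abort(
      sprintf(
        "Unknown table '%s'. Available: %s.",
        name, paste(names(.fixture_registry), collapse = ", ")
      ),
      class = c("feedenergy_error_usage", "feedenergy_error")
    )
  }
  path <- system.file("extdata", info$file, package = "feedenergy")
  if (!nzchar(path)) {
    abort(sprintf("Fixture file '%s' is missing from the installation.", info$file),
      class = c("feedenergy_error_corrupted_fixture", "feedenergy_error"))
  }
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, info$md5)) {
    abort(
      sprintf(
        "Fixture '%s' failed its checksum (%s != %s); the installation is corrupted.",
        info$file, md5, info$md5
      ),
      class = c("feedenergy_error_corrupted_fixture", "feedenergy_error")
    )
  }
  x <- readr::read_csv(path, col_types = info$col_types, progress = FALSE)
  x <- info$post(x)
  attr(x, "provenance") <- info$provenance
  x
}

#' List the packaged reference tables
#'
#' @return A tibble with the canonical name, source file and provenance of
#'   every packaged table.
#' @examples
#' feed_table_names()
#' @export
feed_table_names <- function() {
  tibble(
    name = names(.fixture_registry),
    file = purrr::map_chr(.fixture_registry, "file"),
    provenance = purrr::map_chr(.fixture_registry, "provenance")
  )
}

.parse_p_label <- function(label) {
  suppressWarnings(as.numeric(sub("^<\\s*", "", label)))
}

.fixture_registry <- list(
  ingredients = list(
    file = "table1_ingredients.csv",
    md5 = "76ae385b5cc184bbab3e08a6c3573a9f",
    col_types = "cddddddd",
    provenance = "Chemical composition of 20 feed ingredients (%, DM basis)",
    post = function(x) { validate_ingredients(x); x }
  ),
  experimental_diets = list(
    file = "table2_experimental_diets.csv",
    md5 = "739dc1c99c6e102cdd2f966495020e5b",
    col_types = "ccdl",
    provenance = "Formulations of 20 experimental diets (%, DM basis)",
    post = function(x) { validate_formulations(x); x }
  ),
  validation_diets = list(
    file = "table3_validation_diets.csv",
    md5 = "0b02489cf45116681269287a1e73d8a7",
    col_types = "ccdl",
    provenance = "Formulations of 10 validation diets (%, DM basis)",
    post = function(x) { validate_formulations(x); x }
  ),
  diet_composition = list(
    file = "diet_composition.csv",
    md5 = "629d59f7d69925f4b2e584d284be4595",
    col_types = "cdddddd",
    provenance = "Analyzed chemical composition of all 30 diets (%, DM basis)",
    post = function(x) x
  ),
  balance = list(
    file = "table4_balance.csv",
    md5 = "23743fc7f09460ed3bbc149c78571b68",
    col_types = "ciicdddd",
    provenance = "Per-diet energy balance of growing pigs (kcal/d, DM basis)",
    post = function(x) { validate_balance(x); x }
  ),
  ingredient_energy = list(
    file = "table5_ingredient_energy.csv",
    md5 = "596ca300ab73bd9ae352304e5bcda6aa",
    col_types = "cdddddddddddddd",
    provenance = "In vitro and in vivo energetic values of 20 ingredients (kcal/kg DM)",
    post = function(x) x
  ),
  agreement = list(
    file = "table6_agreement.csv",
    md5 = "8c1b1a4a6d4c0f90ec36e56d3441903c",
    col_types = "ccdd",
    provenance = "Determined vs. calculated energy of validation diets (kcal/kg DM)",
    post = function(x) x
  ),
  prediction = list(
    file = "table7_prediction.csv",
    md5 = "4de396b2fab0cce658d40493f691a92c",
    col_types = "ccdddc",
    provenance = "Determined vs. predicted DE and ME of validation diets (kcal/kg DM)",
    post = function(x) mutate(x, p_value = .parse_p_label(.data$p_label))
  )
)
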