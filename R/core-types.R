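#' Record schemas and invariant checks
#'
#' The pipeline works on four kinds of tabular records, all energies on a
#' dry-matter (DM) basis:
#'
#' * **Ingredient composition** — one row per feed ingredient:
#'   `ingredient_id`, `dm` (DM % of as-fed), `ge` (gross energy, kcal/kg DM)
#'   and the proximate analytes `cp`, `ee`, `ash`, `ndf`, `adf` (% of DM).
#' * **Diet formulation** — long format, one row per diet component:
#'   `diet_id`, `ingredient_id`, `inclusion` (% of diet DM) and
#'   `energy_free` (`TRUE` for mineral/vitamin supplements such as dicalcium
#'   phosphate, limestone, salt and premix, which contribute no energy to
#'   weighted sums).
#' * **Balance observation** — one pig-period energy balance record:
#'   `pig_id`, `batch` (1–2), `period` (1–3), `diet_id`, `dmi` (DM intake,
#'   kg/d), `gei` (GE intake, kcal/d), `geo` (fecal GE output, kcal/d),
#'   `geu` (urinary GE output, kcal/d).
#' * **In vitro run** — one digestion-tube record: `sample_id`, `w_t`
#'   (sample DM mass, kg), `ge_t` (sample GE in the tube, kcal), `ge_r`
#'   (GE of the defatted dried residue, kcal), `ge_e` (GE of the
#'   enzyme-blank residue, kcal).
#'
#' The `validate_*()` functions check the schema and physical invariants of
#' a tibble of records and return the (tibble-coerced) input invisibly, so
#' they can be dropped into a pipe. They are called internally by every
#' computation that consumes these records.
#'
#' @param x A data frame of records.
#' @param tol Tolerance on each diet's inclusion total around 100 (%).
#' @return The validated input as a tibble, invisibly.
#' @examples
#' validate_ingredients(load_feed_table("ingredients"))
#' @name validate
NULL

stop_invalid <- function(msg, class) {
  abort(msg, class = c(class, "feedenergy_error"))
}

require_columns <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    stop_invalid(
      sprintf(
        "%s records lack required column(s): %s",
        what, paste(missing, collapse = ", ")
      ),
      "feedenergy_error_schema"
    )
  }
}

#' @rdname validate
#' @export
validate_ingredients <- function(x) {
  x <- as_tibble(x)
  require_columns(x, c("ingredient_id", "dm", "ge"), "Ingredient composition")
  if (any(x$ge <= 0)) {
    stop_invalid("Gross energy (ge) must be positive for every ingredient.",
      "feedenergy_error_invalid_record")
  }
  if (any(x$dm <= 0 | x$dm > 100)) {
    stop_invalid("DM must lie in (0, 100] percent.",
      "feedenergy_error_invalid_record")
  }
  analytes <- intersect(c("cp", "ee", "ash", "ndf", "adf"), names(x))
  for (a in analytes) {
    if (any(x[[a]] < 0 | x[[a]] > 100, na.rm = TRUE)) {
      stop_invalid(sprintf("Analyte '%s' must lie in [0, 100] percent.", a),
        "feedenergy_error_invalid_record")
    }
  }
  if (anyDuplicated(x$ingredient_id) > 0) {
    stop_invalid("Duplicated ingredient_id in ingredient table.",
      "feedenergy_error_invalid_record")
  }
  invisible(x)
}

#' @rdname validate
#' @export
validate_formulations <- function(x, tol = 0.05) {
  x <- as_tibble(x)
  require_columns(x, c("diet_id", "ingredient_id", "inclusion", "energy_free"),
    "Diet formulation")
  if (any(x$inclusion < 0)) {
    stop_invalid("Inclusions must be non-negative.",
      "feedenergy_error_invalid_record")
  }
  totals <- x %>%
    group_by(.data$diet_id) %>%
    summarise(total = sum(.data$inclusion), .groups = "drop")
  bad <- totals %>% filter(abs(.data$total - 100) > tol)
  if (nrow(bad) > 0) {
    stop_invalid(
      sprintf(
        "Inclusions must sum to 100 (+/- %.2f); off for diet(s): %s",
        tol, paste(bad$diet_id, collapse = ", ")
      ),
      "feedenergy_error_invalid_record"
    )
  }
  invisible(x)
}

#' @rdname validate
#' @export
validate_balance <- function(x) {
  x <- as_tibble(x)
  require_columns(x, c("pig_id", "diet_id", "dmi", "gei", "geo", "geu"),
    "Balance")
  if (any(x$dmi <= 0)) {
    bad <- x$pig_id[x$dmi <= 0]
    stop_invalid(
      sprintf("Non-positive DM intake for pig(s): %s",
        paste(unique(bad), collapse = ", ")),
      "feedenergy_error_invalid_record"
    )
  }
  if (any(x$gei <= 0)) {
    stop_invalid("GE intake must be positive.",
      "feedenergy_error_invalid_record")
  }
  if (any(x$geo < 0 | x$geo >= x$gei)) {
    bad <- x$pig_id[x$geo < 0 | x$geo >= x$gei]
    stop_invalid(
      sprintf(
        "Fecal GE output must satisfy 0 <= geo < gei; violated for pig(s): %s",
        paste(unique(bad), collapse = ", ")
      ),
      "feedenergy_error_implausible_balance"
    )
  }
  if (any(x$geu < 0 | x$geu >= x$gei - x$geo)) {
    bad <- x$pig_id[x$geu < 0 | x$geu >= x$gei - x$geo]
    stop_invalid(
      sprintf(
        "Urinary GE output must satisfy 0 <= geu < gei - geo; violated for pig(s): %s",
        paste(unique(bad), collapse = ", ")
      ),
      "feedenergy_error_implausible_balance"
    )
  }
  invisible(x)
}

#' @rdname validate
#' @export
validate_invitro <- function(x) {
  x <- as_tibble(x)
  require_columns(x, c("sample_id", "w_t", "ge_t", "ge_r", "ge_e"), "In vitro")
  if (any(x$w_t <= 0)) {
    stop_invalid("Tube sample mass w_t must be positive.",
      "feedenergy_error_invalid_record")
  }
  if (any(x$ge_t <= 0)) {
    stop_invalid("Tube sample energy ge_t must be positive.",
      "feedenergy_error_invalid_record")
  }
  if (any(x$ge_r < 0) || any(x$ge_e < 0)) {
    stop_invalid("Residue and blank energies must be non-negative.",
      "feedenergy_error_invalid_record")
  }
  invisible(x)
}
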