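#' Blank-corrected in vitro digestible energy
#'
#' For each digestion-tube record, the energy disappearance per kg of
#' sample DM, corrected for the residue the digestive enzymes themselves
#' leave behind:
#' `ivde = ((ge_t - ge_r) + ge_e) / w_t` (kcal/kg DM), where `ge_t` is the
#' sample energy placed in the tube, `ge_r` the energy of the defatted
#' dried residue and `ge_e` the residue energy of an enzyme-only blank run
#' in the same batch. IVDE can never exceed `(ge_t + ge_e) / w_t`; a
#' residue richer than sample plus blank (`ge_r > ge_t + ge_e`, i.e. a
#' negative apparent digestibility) triggers a suspicious-residue warning
#' but the value is still returned.
#'
#' @param runs A tibble of in vitro runs (see [validate_invitro()]).
#' @return The input with an `ivde` column appended.
#' @examples
#' runs <- tibble::tibble(
#'   sample_id = "corn", w_t = 0.002, ge_t = 7.85, ge_r = 0.1, ge_e = 0.05
#' )
#' compute_ivde(runs)
#' @export
compute_ivde <- function(runs) {
  runs <- as_tibble(runs)
  validate_invitro(runs)
  suspicious <- runs$ge_r > runs$ge_t + runs$ge_e
  if (any(suspicious)) {
    warn(
      sprintf(
        "Residue energy exceeds sample + blank energy (negative digestibility) for sample(s): %s",
        paste(unique(runs$sample_id[suspicious]), collapse = ", ")
      ),
      class = "feedenergy_warning_suspicious_residue"
    )
  }
  runs %>%
    mutate(ivde = ((.data$ge_t - .data$ge_r) + .data$ge_e) / .data$w_t)
}

#' Replicate summary of in vitro runs
#'
#' Per-tube IVDE values are computed with [compute_ivde()] and summarised
#' per sample: replicate count, mean IVDE and CV (`100 * sd / mean`).
#' Samples whose CV exceeds `cv_flag` are marked as protocol anomalies
#' (replicated tube digests of a homogeneous ground sample should agree to
#' well under 5%). Samples with a single tube get `cv = NA` and a message.
#'
#' @param runs A tibble of in vitro runs.
#' @param cv_flag CV (%) above which a sample is flagged.
#' @return One row per sample: `sample_id`, `n_runs`, `ivde`, `cv`,
#'   `flagged`.
#' @examples
#' cfg <- simulation_config(seed = 1)
#' panel <- simulate_ingredients(cfg)
#' runs <- simulate_invitro_runs(cfg, panel)
#' ivde_summary(runs)
#' @export
ivde_summary <- function(runs, cv_flag = 5) {
  per_run <- compute_ivde(runs)
  out <- per_run %>%
    group_by(.data$sample_id) %>%
    summarise(
      n_runs = dplyr::n(),
      cv = 100 * sd(.data$ivde) / mean(.data$ivde),
      ivde = mean(.data$ivde),
      .groups = "drop"
    ) %>%
    mutate(flagged = !is.na(.data$cv) & .data$cv > cv_flag) %>%
    select("sample_id", "n_runs", "ivde", "cv", "flagged")
  singles <- out$sample_id[out$n_runs < 2]
  if (length(singles) > 0) {
    inform(sprintf(
      "CV undefined for sample(s) with a single replicate: %s",
      paste(singles, collapse = ", ")
    ))
  }
  if (any(out$flagged)) {
    warn(
      sprintf(
        "Replicate CV above %s%% (protocol anomaly) for sample(s): %s",
        format(cv_flag), paste(out$sample_id[out$flagged], collapse = ", ")
      ),
      class = "feedenergy_warning_protocol_anomaly"
    )
  }
  out
}
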