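#' Configuration for a synthetic digestibility study
#'
#' Bundles every knob of the synthetic-study generator. The defaults
#' emulate the reference study: a 20-ingredient panel (6 cereals, 11
#' protein feeds, 3 brans), gross energies centred on 4,666 kcal/kg DM and
#' truncated to the observed 4,000–5,800 range, an approximately linear
#' IVDE-to-DE relationship (slope 1.001, offset 180 kcal/kg DM) with
#' class-level IVDE offsets (near zero for cereals, strongly negative
#' bias for protein meals, mild for brans, mirroring the consistent
#' in vitro underestimation of protein feeds), in vivo replicate CVs
#' spanning 0.7–6.5% and in vitro CVs 0.1–1.4%, and a 2-batch x 3-period
#' Youden-square balance design with 6 replicates per diet where daily
#' feed allowance is 4% of initial body weight.
#'
#' @param seed Integer seed; every generator call is internally seeded so
#'   identical configs reproduce identical studies byte for byte.
#' @param n_cereal,n_protein,n_bran Panel sizes per ingredient class.
#' @param ge_mean,ge_sd,ge_range Gross-energy prior (kcal/kg DM),
#'   truncated-normal.
#' @param digestibility_priors Named list of `c(min, max)` uniform priors
#'   on the true energy digestibility per class.
#' @param me_de_range Range of the true ME:DE ratio.
#' @param slope_true,intercept_true True linear map
#'   `DE = slope_true * IVDE + intercept_true + class_offset`; the
#'   generator inverts it to assign each ingredient's true IVDE.
#' @param class_offsets Named numeric class offsets (kcal/kg DM) added to
#'   the map; positive values depress IVDE relative to DE.
#' @param invivo_cv_range,invitro_cv_range Ranges (%) the per-diet in vivo
#'   and per-sample in vitro replicate CVs are drawn from.
#' @param n_batches,n_periods Youden-square layout; replicates per diet is
#'   their product.
#' @param n_invitro_reps Digestion tubes per sample.
#' @param bw_mean,bw_sd Initial body weight (kg) of the pigs.
#' @param dmi_fraction Daily feed allowance as a fraction of body weight
#'   (as-fed); intake is converted to DM with `dm_fraction`.
#' @param dm_fraction Mean diet DM content (fraction of as-fed).
#' @param test_inclusion Test-ingredient inclusion (%) in substitution
#'   diets; the basal cereal fills the remainder next to a fixed 3%
#'   energy-free supplement block.
#' @param direct_inclusion Test-ingredient inclusion (%) in direct
#'   (near-sole) cereal diets.
#' @param n_validation Number of mixed validation diets (3–6 ingredients
#'   each).
#' @return A list of class `feed_sim_config`.
#' @examples
#' simulation_config(seed = 42)
#' @export
simulation_config <- function(seed = 1,
                              n_cereal = 6, n_protein = 11, n_bran = 3,
                              ge_mean = 4666, ge_sd = 300,
                              ge_range = c(4000, 5800),
                              digestibility_priors = list(
                                cereal = c(0.86, 0.94),
                                protein = c(0.80, 0.92),
                                bran = c(0.55, 0.82)
                              ),
                              me_de_range = c(0.90, 0.98),
                              slope_true = 1.001, intercept_true = 180,
                              class_offsets = c(cereal = 0, protein = 300,
                                bran = 100),
                              invivo_cv_range = c(0.7, 6.5),
                              invitro_cv_range = c(0.1, 1.4),
                              n_batches = 2, n_periods = 3,
                              n_invitro_reps = 5,
                              bw_mean = 37.3, bw_sd = 4.7,
                              dmi_fraction = 0.04, dm_fraction = 0.88,
                              test_inclusion = 25, direct_inclusion = 97,
                              n_validation = 10) {
  cfg <- list(
    seed = as.integer(seed),
    n_cereal = n_cereal, n_protein = n_protein, n_bran = n_bran,
    ge_mean = ge_mean, ge_sd = ge_sd, ge_range = ge_range,
    digestibility_priors = digestibility_priors,
    me_de_range = me_de_range,
    slope_true = slope_true, intercept_true = intercept_true,
    class_offsets = class_offsets,
    invivo_cv_range = invivo_cv_range,
    invitro_cv_range = invitro_cv_range,
    n_batches = as.integer(n_batches), n_periods = as.integer(n_periods),
    reps_per_diet = as.integer(n_batches) * as.integer(n_periods),
    n_invitro_reps = as.integer(n_invitro_reps),
    bw_mean = bw_mean, bw_sd = bw_sd,
    dmi_fraction = dmi_fraction, dm_fraction = dm_fraction,
    test_inclusion = test_inclusion, direct_inclusion = direct_inclusion,
    n_validation = as.integer(n_validation)
  )
  bad_cv <- any(unlist(cfg[c("invivo_cv_range", "invitro_cv_range")]) < 0)
  bad_prior <- any(vapply(digestibility_priors,
    function(p) p[1] <= 0 || p[2] > 1 || p[1] > p[2], logical(1)))
  if (bad_cv || bad_prior || ge_range[1] <= 0 || ge_range[1] >= ge_range[2]) {
    abort("Degenerate simulation priors (negative CVs, impossible digestibility or GE range).",
      class = c("feedenergy_error_config", "feedenergy_error"))
  }
  structure(cfg, class = "feed_sim_config")
}

# truncated normal by resampling; bounds are hard limits of the prior
.rnorm_trunc <- function(n, mean, sd, range) {
  x <- rnorm(n, mean, sd)
  for (i in seq_len(50)) {
    out <- x < range[1] | x > range[2]
    if (!any(out)) break
    x[out] <- rnorm(sum(out), mean, sd)
  }
  pmin(pmax(x, range[1]), range[2])
}

# unit-mean multiplicative log-normal noise at relative sd cv
.lognorm_factor <- function(n, cv) {
  if (all(cv == 0)) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulate an ingredient panel with ground-truth energies
#'
#' Draws ingredient classes, proximate composition and gross energy from
#' the configured priors, assigns each ingredient a true digestibility
#' (uniform within its class prior) and ME:DE ratio, and back-computes the
#' true IVDE from the configured linear map
#' `DE = slope_true * IVDE + intercept_true + class_offset`. With all
#' class offsets zero the true IVDE-DE relationship is exactly linear.
#'
#' @param config A [simulation_config()].
#' @return A tibble with the ingredient-composition columns plus `class`
#'   and the ground truth `de_true`, `me_true`, `ivde_true` (kcal/kg DM).
#' @examples
#' simulate_ingredients(simulation_config(seed = 1))
#' @export
simulate_ingredients <- function(config) {
  stopifnot(inherits(config, "feed_sim_config"))
  set.seed(config$seed)
  classes <- rep(c("cereal", "protein", "bran"),
    c(config$n_cereal, config$n_protein, config$n_bran))
  n <- length(classes)
  ge <- .rnorm_trunc(n, config$ge_mean, config$ge_sd, config$ge_range)
  d_true <- vapply(classes, function(cl) {
    p <- config$digestibility_priors[[cl]]
    runif(1, p[1], p[2])
  }, numeric(1))
  me_de <- runif(n, config$me_de_range[1], config$me_de_range[2])
  de_true <- ge * unname(d_true)
  offsets <- config$class_offsets[classes]
  ivde_true <- (de_true - config$intercept_true - offsets) / config$slope_true
  cp <- c(cereal = 11, protein = 48, bran = 16)[classes] + rnorm(n, 0, 2)
  ndf <- c(cereal = 11, protein = 20, bran = 25)[classes] + rnorm(n, 0, 3)
  tibble(
    ingredient_id = sprintf("%s_%02d", classes, stats::ave(
      seq_len(n), classes, FUN = seq_along)),
    class = classes,
    dm = runif(n, 87, 93),
    ge = ge,
    cp = pmax(cp, 1),
    ee = runif(n, 1, 6),
    ash = runif(n, 1.5, 9),
    ndf = pmax(ndf, 2),
    adf = pmax(ndf / 2.5 + rnorm(n, 0, 1), 0.5),
    de_true = de_true,
    me_true = de_true * me_de,
    ivde_true = unname(ivde_true)
  )
}

#' Build the study's diet formulations from a simulated panel
#'
#' Mirrors the reference design: every cereal gets a near-sole direct diet
#' (`direct_inclusion`% plus a 3% energy-free supplement block); every
#' other ingredient gets a substitution diet in which it replaces part of
#' the first cereal (the basal); `n_validation` mixed diets combine 3–6
#' random energetic ingredients. Supplements (dicalcium phosphate,
#' limestone, salt, premix) are energy-free.
#'
#' @param config A [simulation_config()].
#' @param ingredients Panel from [simulate_ingredients()].
#' @return A long-format formulation tibble. Experimental diets are
#'   `d<ingredient_id>`, validation diets `v1..vN`; the basal diet is the
#'   first cereal's direct diet.
#' @examples
#' cfg <- simulation_config(seed = 1)
#' simulate_formulations(cfg, simulate_ingredients(cfg))
#' @export
simulate_formulations <- function(config, ingredients) {
  stopifnot(inherits(config, "feed_sim_config"))
  set.seed(config$seed + 1L)
  supplements <- tibble(
    ingredient_id = c("dicalcium_phosphate", "limestone", "salt", "premix"),
    inclusion = c(1.2, 1.2, 0.46, 0.14),
    energy_free = TRUE
  )
  basal <- ingredients$ingredient_id[ingredients$class == "cereal"][1]
  energetic_total <- 100 - sum(supplements$inclusion)
  one_diet <- function(diet_id, ids, incl) {
    bind_rows(
      tibble(ingredient_id = ids, inclusion = incl, energy_free = FALSE),
      supplements
    ) %>% mutate(diet_id = diet_id, .before = 1)
  }
  exp_diets <- purrr::map2(
    ingredients$ingredient_id, ingredients$class,
    function(id, cl) {
      if (cl == "cereal") {
        one_diet(paste0("d_", id), id, energetic_total)
      } else {
        one_diet(
          paste0("d_", id), c(id, basal),
          c(config$test_inclusion, energetic_total - config$test_inclusion)
        )
      }
    }
  )
  val_diets <- purrr::map(seq_len(config$n_validation), function(i) {
    k <- sample(3:6, 1)
    ids <- sample(ingredients$ingredient_id, k)
    w <- runif(k, 0.5, 2)
    one_diet(paste0("v", i), ids, energetic_total * w / sum(w))
  })
  out <- bind_rows(exp_diets, val_diets)
  validate_formulations(out)
  out
}

# ground-truth diet energies implied by additivity over the panel
.diet_truth <- function(ingredients, formulations) {
  truth <- calculated_diet_energy(
    formulations,
    ingredients %>% select("ingredient_id", ge_d = "ge", de_d = "de_true",
      me_d = "me_true", ivde_d = "ivde_true"),
    value_cols = c("ge_d", "de_d", "me_d", "ivde_d")
  )
  truth %>% mutate(d = .data$de_d / .data$ge_d, m = .data$me_d / .data$ge_d)
}

# cyclic Youden-square allocation: pigs x periods within a batch, each diet
# once per batch-period column, no pig repeating a diet
.youden_layout <- function(n_diets, n_batches, n_periods) {
  if (n_periods > n_diets) {
    abort("Infeasible layout: more periods than diets means a pig must repeat a diet.",
      class = c("feedenergy_error_design", "feedenergy_error"))
  }
  shifts <- integer(0)
  s <- 1L
  while (length(shifts) < n_batches) {
    mults <- (s * seq_len(n_periods - 1)) %% n_diets
    if (all(mults != 0)) shifts <- c(shifts, s)
    s <- s + 1L
    if (s > 10L * n_diets) {
      abort("Infeasible layout: no valid cyclic shift found.",
        class = c("feedenergy_error_design", "feedenergy_error"))
    }
  }
  purrr::map_dfr(seq_len(n_batches), function(b) {
    purrr::map_dfr(seq_len(n_periods), function(p) {
      tibble(
        batch = b, period = p, pig = seq_len(n_diets),
        diet_index = ((seq_len(n_diets) - 1 + (p - 1) * shifts[b]) %% n_diets) + 1
      )
    })
  })
}

#' Simulate a Youden-square balance study
#'
#' Allocates diets to pigs in a cyclic row-column (Youden square) layout —
#' every diet once per batch-period, no pig receiving a diet twice — and
#' generates per-pig energy balances from the ground-truth diet energies:
#' `gei = dmi * ge_d`, fecal output `geo = gei * (1 - d)` and urinary
#' output `geu = gei * (d - m)`, each excretion perturbed by unit-mean
#' multiplicative log-normal noise. The fecal noise CV is calibrated per
#' diet so that the induced replicate CV of DE matches a draw from the
#' configured in vivo range (`cv_geo = cv_de * d / (1 - d)`); urinary
#' noise uses an independent draw from the same range. Guards resample any
#' excretion that would violate the balance invariants.
#'
#' @param config A [simulation_config()].
#' @param ingredients Panel from [simulate_ingredients()].
#' @param formulations Diets from [simulate_formulations()].
#' @param noise Overall noise multiplier; `0` yields exact noiseless
#'   balances (every pig reproduces the true diet energies).
#' @return A balance-observation tibble (`pig_id`, `batch`, `period`,
#'   `diet_id`, `dmi`, `gei`, `geo`, `geu`).
#' @examples
#' cfg <- simulation_config(seed = 1)
#' panel <- simulate_ingredients(cfg)
#' diets <- simulate_formulations(cfg, panel)
#' simulate_balance_study(cfg, panel, diets)
#' @export
simulate_balance_study <- function(config, ingredients, formulations,
                                   noise = 1) {
  stopifnot(inherits(config, "feed_sim_config"))
  set.seed(config$seed + 2L)
  truth <- .diet_truth(ingredients, formulations)
  n_diets <- nrow(truth)
  layout <- .youden_layout(n_diets, config$n_batches, config$n_periods)
  cv_de_target <- runif(n_diets, config$invivo_cv_range[1],
    config$invivo_cv_range[2]) / 100 * noise
  cv_me_target <- runif(n_diets, config$invivo_cv_range[1],
    config$invivo_cv_range[2]) / 100 * noise
  obs <- layout %>%
    mutate(
      diet_id = truth$diet_id[.data$diet_index],
      d = truth$d[.data$diet_index],
      m = truth$m[.data$diet_index],
      ge_d = truth$ge_d[.data$diet_index],
      cv_geo = cv_de_target[.data$diet_index] * .data$d / (1 - .data$d),
      cv_geu = cv_me_target[.data$diet_index],
      pig_id = sprintf("b%d_p%02d", .data$batch, .data$pig),
      bw = .rnorm_trunc(dplyr::n(), config$bw_mean, config$bw_sd,
        config$bw_mean + c(-3, 3) * config$bw_sd),
      dmi = config$dmi_fraction * .data$bw * config$dm_fraction,
      gei = .data$dmi * .data$ge_d,
      geo = .data$gei * (1 - .data$d) *
        .lognorm_factor(dplyr::n(), .data$cv_geo),
      geu = .data$gei * (.data$d - .data$m) *
        .lognorm_factor(dplyr::n(), .data$cv_geu)
    )
  # truncation guards: keep excretions within the balance invariants
  obs <- obs %>%
    mutate(
      geo = pmin(.data$geo, 0.95 * .data$gei),
      geu = pmin(.data$geu, 0.95 * (.data$gei - .data$geo))
    ) %>%
    select("pig_id", "batch", "period", "diet_id", "dmi", "gei", "geo", "geu")
  validate_balance(obs)
  obs
}

#' Simulate replicated in vitro digestion runs
#'
#' Generates `n_invitro_reps` digestion tubes per ingredient. Tube mass is
#' 2 g DM for cereals (as for diets) and 1 g for other ingredients; the
#' tube sample energy is `w_t` times the ingredient GE concentration. Each
#' batch carries one enzyme blank whose residue energy `ge_e` is shared by
#' its tubes, and the tube residue energy is back-computed from the
#' ingredient's true IVDE perturbed by multiplicative replicate noise at a
#' per-sample CV drawn from the configured in vitro range — so
#' [compute_ivde()] recovers exactly the noisy replicate value, and
#' changing the blank magnitude leaves IVDE unchanged by construction.
#'
#' @param config A [simulation_config()].
#' @param ingredients Panel from [simulate_ingredients()].
#' @param noise Overall noise multiplier; `0` makes every tube reproduce
#'   the true IVDE exactly.
#' @return An in vitro run tibble (`sample_id`, `batch`, `w_t`, `ge_t`,
#'   `ge_r`, `ge_e`).
#' @examples
#' cfg <- simulation_config(seed = 1)
#' simulate_invitro_runs(cfg, simulate_ingredients(cfg))
#' @export
simulate_invitro_runs <- function(config, ingredients, noise = 1) {
  stopifnot(inherits(config, "feed_sim_config"))
  set.seed(config$seed + 3L)
  reps <- config$n_invitro_reps
  blank_ge <- runif(config$n_batches, 0.02, 0.06)
  runs <- ingredients %>%
    select("ingredient_id", "class", "ge", "ivde_true") %>%
    tidyr::uncount(reps, .id = "rep") %>%
    mutate(
      sample_id = .data$ingredient_id,
      batch = ((.data$rep - 1) %% config$n_batches) + 1L,
      w_t = ifelse(.data$class == "cereal", 0.002, 0.001),
      ge_t = .data$w_t * .data$ge,
      cv = runif(dplyr::n(), config$invitro_cv_range[1],
        config$invitro_cv_range[2]) / 100 * noise,
      ivde_rep = .data$ivde_true * .lognorm_factor(dplyr::n(), .data$cv),
      ge_e = blank_ge[.data$batch],
      ge_r = .data$ge_t - .data$w_t * .data$ivde_rep + .data$ge_e
    ) %>%
    select("sample_id", "batch", "w_t", "ge_t", "ge_r", "ge_e")
  validate_invitro(runs)
  runs
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_ingredients()],
#' [simulate_formulations()], [simulate_balance_study()] and
#' [simulate_invitro_runs()] under one configuration, together with the
#' additivity-implied ground-truth diet energies.
#'
#' @param config A [simulation_config()].
#' @param noise Overall noise multiplier applied to both stages.
#' @return A list with `config`, `ingredients`, `formulations`, `balance`,
#'   `invitro` and `diet_truth`.
#' @examples
#' study <- simulate_study(simulation_config(seed = 7))
#' names(study)
#' @export
simulate_study <- function(config = simulation_config(), noise = 1) {
  ingredients <- simulate_ingredients(config)
  formulations <- simulate_formulations(config, ingredients)
  balance <- simulate_balance_study(config, ingredients, formulations,
    noise = noise)
  invitro <- simulate_invitro_runs(config, ingredients, noise = noise)
  list(
    config = config,
    ingredients = ingredients,
    formulations = formulations,
    balance = balance,
    invitro = invitro,
    diet_truth = .diet_truth(ingredients, formulations)
  )
}
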