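test_that("identical configs reproduce identical studies", {
  cfg <- simulation_config(seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$ingredients, s2$ingredients)
  expect_identical(s1$formulations, s2$formulations)
  expect_identical(s1$balance, s2$balance)
  expect_identical(s1$invitro, s2$invitro)
})

test_that("generated panels respect the configured envelopes", {
  for (seed in 1:40) {
    ing <- simulate_ingredients(simulation_config(seed = seed))
    expect_true(all(ing$ge >= 4000 & ing$ge <= 5800))
    expect_true(all(ing$me_true / ing$de_true >= 0.90 &
        ing$me_true / ing$de_true <= 0.98))
    expect_true(all(ing$de_true <= ing$ge))
    expect_true(all(ing$ivde_true > 0))
  }
  ing <- simulate_ingredients(simulation_config(seed = 1))
  expect_equal(nrow(ing), 20)
  expect_equal(as.integer(table(ing$class)[c("cereal", "protein", "bran")]),
    c(6L, 11L, 3L))
})

test_that("zero class offsets make the true IVDE-DE relationship exactly linear", {
  cfg <- simulation_config(seed = 13,
    class_offsets = c(cereal = 0, protein = 0, bran = 0))
  ing <- simulate_ingredients(cfg)
  fit <- fit_calibration(
    tibble::tibble(ivde = ing$ivde_true, de = ing$de_true), "de")
  expect_equal(fit$slope, cfg$slope_true, tolerance = 1e-10)
  expect_equal(fit$intercept, cfg$intercept_true, tolerance = 1e-7)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("degenerate configurations are rejected", {
  expect_error(simulation_config(invivo_cv_range = c(-1, 2)),
    class = "feedenergy_error_config")
  expect_error(
    simulation_config(digestibility_priors = list(cereal = c(0.9, 1.2),
      protein = c(0.8, 0.9), bran = c(0.6, 0.8))),
    class = "feedenergy_error_config"
  )
  expect_error(simulation_config(ge_range = c(5000, 4000)),
    class = "feedenergy_error_config")
})

test_that("the Youden allocation is balanced and never repeats a diet on a pig", {
  cfg <- simulation_config(seed = 3)
  study <- simulate_study(cfg)
  bal <- study$balance
  # every diet exactly once per batch-period cell
  cell <- dplyr::count(bal, batch, period, diet_id)
  expect_true(all(cell$n == 1))
  # six replicates per diet = 2 batches x 3 periods
  per_diet <- dplyr::count(bal, diet_id)
  expect_true(all(per_diet$n == cfg$reps_per_diet))
  # no pig sees a diet twice
  per_pig <- dplyr::count(bal, pig_id, diet_id)
  expect_true(all(per_pig$n == 1))
  # infeasible layout: fewer diets than periods
  tiny <- simulation_config(seed = 3, n_cereal = 1, n_protein = 0,
    n_bran = 0, n_validation = 0)
  ing <- simulate_ingredients(tiny)
  frm <- simulate_formulations(tiny, ing)
  expect_error(simulate_balance_study(tiny, ing, frm),
    class = "feedenergy_error_design")
})

test_that("noiseless studies are internally exact end to end", {
  cfg <- simulation_config(seed = 17)
  study <- simulate_study(cfg, noise = 0)
  agg <- aggregate_diet_energy(study$balance, screen = FALSE)
  chk <- dplyr::left_join(agg, study$diet_truth, by = "diet_id",
    suffix = c("", "_true"))
  expect_equal(chk$de_d, chk$de_d_true, tolerance = 1e-10)
  expect_equal(chk$me_d, chk$me_d_true, tolerance = 1e-10)
  expect_true(all(abs(chk$cv_de) < 1e-10))

  iv <- ivde_summary(study$invitro)
  chk_iv <- dplyr::left_join(iv,
    dplyr::select(study$ingredients, sample_id = ingredient_id, ivde_true),
    by = "sample_id")
  expect_equal(chk_iv$ivde, chk_iv$ivde_true, tolerance = 1e-10)

  # additivity: determined validation-diet energy equals the weighted sum
  # of true ingredient energies exactly
  report <- run_pipeline("simulate", config = cfg, noise = 0)
  val <- report$validation$table
  truth <- study$diet_truth
  expect_equal(val$determined,
    truth$de_d[match(val$diet_id, truth$diet_id)], tolerance = 1e-10)
})

test_that("replicated noisy studies recover diet energies at the t-distribution rate", {
  # coverage oracle: |mean - truth| <= 2 * SEM is a |t_5| <= 2 event for
  # 6 replicates, with probability 2 * pt(2, 5) - 1 = 0.898
  hits <- 0L
  total <- 0L
  for (seed in 1:25) {
    cfg <- simulation_config(seed = seed, n_validation = 0)
    study <- simulate_study(cfg)
    per_obs <- diet_energy(study$balance)
    agg <- per_obs |>
      dplyr::group_by(diet_id) |>
      dplyr::summarise(m = mean(de_d), sem = sd(de_d) / sqrt(dplyr::n()))
    truth <- study$diet_truth
    err <- abs(agg$m - truth$de_d[match(agg$diet_id, truth$diet_id)])
    hits <- hits + sum(err <= 2 * agg$sem)
    total <- total + nrow(agg)
  }
  expect_equal(hits / total, 2 * pt(2, 5) - 1, tolerance = 0.05)
})

test_that("the full pipeline recovers the generating calibration", {
  # one noisy study estimates the slope with an sd of roughly 0.1
  # (rsd ~ 300 kcal/kg over the panel spread), so the estimate is checked
  # per seed at 2.5 sd and for unbiasedness across seeds
  slopes <- vapply(1:8, function(seed) {
    cfg <- simulation_config(seed = seed,
      class_offsets = c(cereal = 0, protein = 0, bran = 0))
    run_pipeline("simulate", config = cfg)$calibration$de$slope
  }, numeric(1))
  expect_true(all(abs(slopes - 1.001) < 0.25))
  expect_equal(mean(slopes), 1.001, tolerance = 0.05 / 1.001)
})

test_that("in vitro replicate CVs stay inside the working envelope", {
  inside <- 0L
  total <- 0L
  for (seed in 1:15) {
    cfg <- simulation_config(seed = seed)
    runs <- simulate_invitro_runs(cfg, simulate_ingredients(cfg))
    cv <- ivde_summary(runs)$cv
    inside <- inside + sum(cv >= 0.05 & cv <= 2.0)
    total <- total + length(cv)
  }
  expect_gte(inside / total, 0.95)
})

test_that("doubling the blank leaves the computed IVDE untouched", {
  cfg <- simulation_config(seed = 41)
  runs <- simulate_invitro_runs(cfg, simulate_ingredients(cfg))
  v0 <- compute_ivde(runs)$ivde
  # the generator books the blank on both sides of the correction
  doubled <- dplyr::mutate(runs, ge_r = ge_r + ge_e, ge_e = 2 * ge_e)
  expect_equal(compute_ivde(doubled)$ivde, v0, tolerance = 1e-12)
})
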