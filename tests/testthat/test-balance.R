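test_that("diet energy reproduces hand arithmetic on the printed balance rows", {
  d1 <- diet_energy(tbl_balance[tbl_balance$diet_id == "d1", ])
  # (5867 - 626) / 1.356 and (5867 - 626 - 123) / 1.356
  expect_equal(d1$de_d, 5241 / 1.356, tolerance = 1e-12)
  expect_equal(d1$me_d, 5118 / 1.356, tolerance = 1e-12)
  expect_equal(d1$de_d, 3865, tolerance = 0.5 / 3865)
  expect_equal(d1$me_d, 3774.3, tolerance = 0.5 / 3774)

  d20 <- diet_energy(tbl_balance[tbl_balance$diet_id == "d20", ])
  expect_equal(d20$ge_d, 4349, tolerance = 0.5 / 4349) # analyzed GE of diet 20
})

test_that("lossless digestion collapses GE, DE and ME", {
  res <- diet_energy(lossless_obs(ge_d = 4200))
  expect_equal(res$de_d, res$ge_d)
  expect_equal(res$me_d, res$ge_d)
  expect_equal(res$d_coef, 1)
})

test_that("energy ordering me <= de <= ge holds across printed and simulated records", {
  all_fix <- diet_energy(tbl_balance)
  expect_true(all(all_fix$me_d <= all_fix$de_d & all_fix$de_d <= all_fix$ge_d))
  sim <- simulate_study(simulation_config(seed = 11))
  all_sim <- diet_energy(sim$balance)
  expect_true(all(all_sim$me_d <= all_sim$de_d & all_sim$de_d <= all_sim$ge_d))
})

test_that("aggregation averages per-observation energies and is order invariant", {
  obs <- dplyr::bind_rows(replicate(6, lossless_obs(), simplify = FALSE)) |>
    dplyr::mutate(pig_id = paste0("p", 1:6), geo = 500, geu = 50)
  agg <- aggregate_diet_energy(obs)
  expect_equal(agg$n_obs, 6)
  expect_equal(agg$de_d, diet_energy(obs[1, ])$de_d)
  expect_equal(agg$cv_de, 0)

  sim <- simulate_study(simulation_config(seed = 5))
  a1 <- aggregate_diet_energy(sim$balance)
  a2 <- aggregate_diet_energy(sim$balance[sample(nrow(sim$balance)), ])
  expect_equal(a1, a2)
})

test_that("replicate CV of DE matches the propagated fecal noise", {
  # half-digestible diet: a 2% multiplicative sd on geo propagates to a
  # cv(de) of about 2% x geo/(gei - geo) = 2%; Monte-Carlo at n = 6
  set.seed(401)
  cvs <- replicate(300, {
    geo <- 2500 * exp(rnorm(6, 0, 0.02) - 0.02^2 / 2)
    obs <- tibble::tibble(
      pig_id = paste0("p", 1:6), batch = 1L, period = 1L, diet_id = "dd",
      dmi = 1.3, gei = 5000, geo = geo, geu = 100
    )
    aggregate_diet_energy(obs, screen = FALSE)$cv_de
  })
  expect_gt(mean(cvs), 1)
  expect_lt(mean(cvs), 4)
})

test_that("in vivo CVs of a default synthetic study have the study's magnitude", {
  sim <- simulate_study(simulation_config(seed = 23))
  agg <- aggregate_diet_energy(sim$balance, screen = FALSE)
  # targets are drawn from 0.7-6.5%; realized CVs at n = 6 scatter around them
  expect_gt(median(agg$cv_de), 0.7)
  expect_lt(median(agg$cv_de), 6.5)
  expect_true(mean(agg$cv_de > 0.2 & agg$cv_de < 10) > 0.9)
})

test_that("the IQR screen uses Tukey hinges and flags gross outliers", {
  s1 <- iqr_screen(c(1, 2, 3, 4, 100))
  expect_equal(s1$flagged, 100)
  expect_equal(s1$kept, c(1, 2, 3, 4))

  expect_length(iqr_screen(rep(7, 6))$flagged, 0)

  # brute-force hinges for {10,11,12,12,13,30}: halves {10,11,12} and
  # {12,13,30} give Q1 = 11, Q3 = 13, fence 8..16
  s2 <- iqr_screen(c(10, 12, 11, 13, 12, 30))
  expect_equal(s2$bounds, c(8, 16))
  expect_equal(s2$flagged, 30)

  expect_warning(
    s3 <- iqr_screen(c(1, 2, 3)),
    class = "feedenergy_warning_screen_skipped"
  )
  expect_equal(s3$kept, c(1, 2, 3))
})

test_that("direct method scales diet digestibility to the ingredient GE", {
  diets <- aggregate_diet_energy(tbl_balance)
  res <- direct_ingredient_energy(diets, tbl_exp_diets, tbl_ingredients,
    diet_ids = paste0("d", 1:6))
  corn <- res[res$ingredient_id == "corn", ]
  expect_equal(corn$de, 3986, tolerance = 5 / 3986) # printed Table value
  rice <- res[res$ingredient_id == "brown_rice", ]
  expect_equal(rice$de, 4034, tolerance = 5 / 4034)
  expect_true(all(res$method == "direct"))

  # lossless diet of an ingredient with ge_ti = ge_d recovers ge_ti
  obs <- lossless_obs(ge_d = 4100)
  diets1 <- aggregate_diet_energy(obs)
  form <- tibble::tibble(
    diet_id = "dd",
    ingredient_id = c("ing", "mineral"),
    inclusion = c(97, 3), energy_free = c(FALSE, TRUE)
  )
  ing <- tibble::tibble(ingredient_id = "ing", dm = 88, ge = 4100)
  out <- direct_ingredient_energy(diets1, form, ing)
  expect_equal(out$de, 4100)

  # low-inclusion diets are refused and redirected
  expect_error(
    direct_ingredient_energy(diets, tbl_exp_diets, tbl_ingredients,
      diet_ids = "d20"),
    class = "feedenergy_error_wrong_method"
  )
})

test_that("substitution method recovers the wheat bran energy from diets 1 and 20", {
  diets <- aggregate_diet_energy(tbl_balance)
  res <- substitution_ingredient_energy(diets, tbl_exp_diets,
    tbl_ingredients, basal_diet = "d1", diet_ids = "d20")
  # hand-derived: p_ti = 0.2519 * 4584 / 4349.0, d_ti via the displacement
  # formula -> about 2,700 kcal/kg; printed mean 2,686 from per-pig averaging
  expect_equal(res$de, 2686, tolerance = 0.006)
  expect_equal(res$p_ti, 0.2519 * 4584 / (5845 / 1.344), tolerance = 1e-12)
})

test_that("substitution identities: p_ti = 1 and no-displacement cases", {
  basal <- tibble::tibble(
    diet_id = "basal", n_obs = 1L, ge_d = 4400, de_d = 3900, me_d = 3800,
    d_coef = 3900 / 4400, m_coef = 3800 / 4400,
    cv_de = NA_real_, cv_me = NA_real_
  )
  # pure-ingredient test diet: p_ti = 1 forces d_ti = d_td
  test_d <- basal |>
    dplyr::mutate(diet_id = "test", ge_d = 4600, de_d = 4000, me_d = 3900,
      d_coef = 4000 / 4600, m_coef = 3900 / 4600)
  diets <- dplyr::bind_rows(basal, test_d)
  form <- tibble::tibble(
    diet_id = c("basal", "test"),
    ingredient_id = c("corn_like", "pure"),
    inclusion = c(100, 100), energy_free = FALSE
  )
  ing <- tibble::tibble(ingredient_id = c("corn_like", "pure"),
    dm = 88, ge = c(4400, 4600))
  res <- substitution_ingredient_energy(diets, form, ing,
    basal_diet = "basal")
  expect_equal(res$p_ti, 1)
  expect_equal(res$de, 4600 * (4000 / 4600)) # ge_ti * d_td
  expect_equal(res$me, 4600 * (3900 / 4600))

  # equal digestibilities: the ingredient inherits d_cd whatever p_ti is
  same_d <- basal |>
    dplyr::mutate(diet_id = "same", ge_d = 4500, de_d = 4500 * 3900 / 4400,
      me_d = 4500 * 3800 / 4400, d_coef = 3900 / 4400, m_coef = 3800 / 4400)
  diets2 <- dplyr::bind_rows(basal, same_d)
  form2 <- tibble::tibble(
    diet_id = c("basal", "same", "same"),
    ingredient_id = c("corn_like", "tester", "corn_like"),
    inclusion = c(100, 30, 70), energy_free = FALSE
  )
  ing2 <- tibble::tibble(ingredient_id = c("corn_like", "tester"),
    dm = 88, ge = c(4400, 4800))
  res2 <- substitution_ingredient_energy(diets2, form2, ing2,
    basal_diet = "basal")
  expect_equal(res2$de, 4800 * 3900 / 4400, tolerance = 1e-12)
})

test_that("substitution guards: bad proportions and missing basal", {
  diets <- aggregate_diet_energy(tbl_balance)
  expect_error(
    substitution_ingredient_energy(diets, tbl_exp_diets, tbl_ingredients,
      basal_diet = "not_a_diet"),
    class = "feedenergy_error_configuration"
  )
  # inflated test-ingredient GE pushes p_ti above 1
  inflated <- tbl_ingredients |>
    dplyr::mutate(ge = ifelse(ingredient_id == "wheat_bran", 40000, ge))
  expect_error(
    suppressWarnings(substitution_ingredient_energy(diets, tbl_exp_diets,
      inflated, basal_diet = "d1", diet_ids = "d20")),
    class = "feedenergy_error_invalid_proportion"
  )
})

test_that("the displacement formula inverts algebraically on every test diet", {
  diets <- aggregate_diet_energy(tbl_balance)
  est <- substitution_ingredient_energy(diets, tbl_exp_diets,
    tbl_ingredients, basal_diet = "d1", diet_ids = paste0("d", 7:20))
  basal <- diets[diets$diet_id == "d1", ]
  ing <- dplyr::left_join(est,
    dplyr::select(tbl_ingredients, ingredient_id, ge), by = "ingredient_id")
  # d_td reconstructed from basal + ingredient coefficients must equal the
  # observed test-diet digestibility exactly
  d_ti <- ing$de / ing$ge
  d_td_back <- basal$d_coef + ing$p_ti * (d_ti - basal$d_coef)
  d_td_obs <- diets$d_coef[match(est$diet_id, diets$diet_id)]
  expect_equal(d_td_back, d_td_obs, tolerance = 1e-12)
})

test_that("noise-free simulated studies recover ingredient energies exactly", {
  report <- run_pipeline("simulate",
    config = simulation_config(seed = 19), noise = 0)
  expect_lt(max(abs(report$recovery$de_error)), 0.1)
  expect_lt(max(abs(report$recovery$me_error)), 0.1)
})
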