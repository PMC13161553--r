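# shared objects for the suite: loading the packaged study once keeps the
# individual test files quick
tbl_ingredients <- load_feed_table("ingredients")
tbl_exp_diets <- load_feed_table("experimental_diets")
tbl_val_diets <- load_feed_table("validation_diets")
tbl_balance <- load_feed_table("balance")
tbl_panel <- load_feed_table("ingredient_energy")
tbl_agreement <- load_feed_table("agreement")
tbl_prediction <- load_feed_table("prediction")

# a minimal single-ingredient trial: one diet, perfectly digestible
lossless_obs <- function(ge_d = 4000, dmi = 1.25) {
  tibble::tibble(
    pig_id = "p1", batch = 1L, period = 1L, diet_id = "dd",
    dmi = dmi, gei = ge_d * dmi, geo = 0, geu = 0
  )
}
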