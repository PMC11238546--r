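# Exchangeable-cation deltas, CDR gain, EDDHA trends, prebound Fe contrast.

test_that("deltas are zero when nothing changes and error on missing cells", {
  ispec <- incubation_sim_spec(
    soil_drift = c(Ca = 0, Mg = 0, Na = 0, K = 0),
    basalt_effect = c(Ca = 0, Mg = 0, Na = 0, K = 0),
    eddha_slope = c(Ca = 0, Mg = 0, Na = 0, K = 0),
    noise_sd = 0)
  rec <- simulate_incubation_dataset(ispec)
  d <- delta_by_treatment(rec, "Ca")
  expect_equal(d$delta, rep(0, 8))
  # dropping day-0 soil rows triggers a named error
  rec2 <- rec[!(rec$day == 0 & rec$treatment == "soil"), ]
  expect_error(delta_by_treatment(rec2, "Ca"), "missing day 0")
})

test_that("SEM propagation follows sqrt(SEM0^2 + SEM20^2)", {
  ispec <- incubation_sim_spec(noise_sd = 3, seed = 17)
  rec <- simulate_incubation_dataset(ispec)
  d <- delta_by_treatment(rec, "Mg")
  cell <- function(tr, lv, day) {
    rec$concentration[rec$element == "Mg" & rec$treatment == tr &
                        rec$eddha_uM == lv & rec$day == day]
  }
  s <- function(x) sd(x) / sqrt(length(x))
  v0 <- cell("soil", 100, 0); v20 <- cell("soil", 100, 20)
  row <- d[d$treatment == "soil" & d$eddha_uM == 100, ]
  expect_equal(row$delta, mean(v20) - mean(v0))
  expect_equal(row$sem, sqrt(s(v0)^2 + s(v20)^2))
})

test_that("cdr_gain recovers the planted fold profile exactly", {
  # defaults plant 2.5-fold at 750 uM (slope = 1.5 x effect / 750)
  rec <- simulate_incubation_dataset(incubation_sim_spec(noise_sd = 0))
  res <- cdr_gain(rec)
  expect_equal(res$by_level$fold_gain[res$by_level$eddha_uM == 0], 1.0)
  expect_equal(res$by_level$fold_gain[res$by_level$eddha_uM == 750], 2.5)
  # linear interior points of the planted profile
  expect_equal(res$by_level$fold_gain[res$by_level$eddha_uM == 100],
               1 + 1.5 * 100 / 750)
  # the statistic only sees deltas: shifting every concentration of an
  # element by a constant changes nothing
  rec2 <- rec
  rec2$concentration[rec2$element == "Ca"] <-
    rec2$concentration[rec2$element == "Ca"] + 500
  expect_equal(cdr_gain(rec2)$by_level$fold_gain,
               res$by_level$fold_gain)
})

test_that("equivalent and molar CO2 weightings are both reported", {
  rec <- simulate_incubation_dataset(incubation_sim_spec(noise_sd = 0))
  res <- cdr_gain(rec)
  # with only Ca/Mg/Na/K the two weightings coincide by construction
  expect_equal(res$by_level$co2_mol_kg, res$by_level$co2_eq_mol_kg)
})

test_that("mg/kg -> mol/kg -> CO2 conversion is self-consistent", {
  d_mg <- c(Ca = 40.078, Mg = 24.305, Na = 22.990, K = 39.098)  # 1 mmol/kg
  res <- cdr_from_cations(d_mg / 1000, basis = "mass")
  expect_equal(res$mol_co2, 2e-3 + 2e-3 + 1e-3 + 1e-3, tolerance = 1e-9)
})

test_that("EDDHA trend calibrates under the null and detects planted slopes", {
  # type-I: planted slope 0, p approximately uniform -> ~5% rejections
  rejections <- 0
  for (s in 1:100) {
    ispec <- incubation_sim_spec(
      basalt_effect = c(Ca = 40, Mg = 12, Na = 2, K = 8),
      eddha_slope = c(Ca = 0, Mg = 0, Na = 0, K = 0),
      noise_sd = 5, seed = 2000 + s)
    rec <- simulate_incubation_dataset(ispec)
    sb <- rec[rec$treatment == "soil+basalt" & rec$day == 20 &
                rec$element == "Ca", ]
    tr <- eddha_trend(sb$eddha_uM, sb$concentration)
    if (tr$p < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections, 15)

  # power: planted positive slope well above noise, n = 12
  detections <- 0
  for (s in 1:100) {
    ispec <- incubation_sim_spec(noise_sd = 5, seed = 3000 + s)
    rec <- simulate_incubation_dataset(ispec)
    sb <- rec[rec$treatment == "soil+basalt" & rec$day == 20 &
                rec$element == "Ca", ]
    tr <- eddha_trend(sb$eddha_uM, sb$concentration)
    if (tr$r > 0 && tr$p < 0.05) detections <- detections + 1
  }
  expect_gte(detections, 90)
})

test_that("perfectly linear values give r = 1", {
  expect_equal(eddha_trend(c(0, 100, 425, 750),
                           c(0, 100, 425, 750) * 0.01)$r, 1.0)
})

make_prebound_fixture <- function(diff, noise_sd = 0, seed = 1) {
  set.seed(seed)
  g <- expand.grid(fe_df_preb = c(FALSE, TRUE),
                   treatment = c("soil", "soil+basalt"),
                   replicate = 1:3, stringsAsFactors = FALSE)
  g$eddha_uM <- 425; g$day <- 20; g$extract <- "hot-water"
  g$element <- "Fe"
  g$concentration <- 10 + ifelse(g$fe_df_preb, 0, diff) +
    ifelse(g$treatment == "soil+basalt", 2, 0) +
    rnorm(nrow(g), 0, noise_sd)
  g
}

test_that("prebound Fe:DF contrast behaves across regimes", {
  # identical arms, zero noise -> F = 0, p = 1
  res0 <- prebound_fe_contrast(make_prebound_fixture(0))
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)
  # planted difference with zero noise -> maximal F
  res1 <- prebound_fe_contrast(make_prebound_fixture(5))
  expect_equal(res1$F, Inf)
  expect_equal(res1$p, 0)
  # noisy 2x2x3 fixture matches a direct aov call
  fx <- make_prebound_fixture(5, noise_sd = 1, seed = 9)
  res2 <- prebound_fe_contrast(fx)
  ref <- summary(aov(concentration ~ factor(fe_df_preb) +
                       factor(treatment), data = fx))[[1]]
  expect_equal(res2$F, ref[1, "F value"])
  expect_equal(res2$p, ref[1, "Pr(>F)"])
  # a missing arm errors
  expect_error(prebound_fe_contrast(fx[!fx$fe_df_preb, ]), "arms")
})
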