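test_that("effect-matched design places each component at its own IC_x", {
  des <- design_effect_matched_mixtures(acarbose_fit(), propolis_fit())
  expect_equal(des$level, c(0.10, 0.30, 0.50, 0.70, 0.90))
  # IC50-matched level is (Dm_a, Dm_b) by definition
  expect_equal(des$c_a[des$level == 0.5], 0.061)
  expect_equal(des$c_b[des$level == 0.5], 1.07)
  # the published lowest-level mixture: 0.012 mM acarbose + 0.015 mg/mL propolis
  expect_equal(round(des$c_a[des$level == 0.1], 3), 0.012)
  expect_equal(round(des$c_b[des$level == 0.1], 3), 0.015)
  # kaempferol's IC10 (cross-checked against the published DRI at fa = 0.26)
  desk <- design_effect_matched_mixtures(acarbose_fit(), kaempferol_fit(),
                                         effect_levels = 0.10)
  expect_equal(desk$c_b, 0.752, tolerance = 1e-3)
  expect_error(design_effect_matched_mixtures(acarbose_fit(), propolis_fit(),
                                              effect_levels = c(0.1, 1)),
               "inside \\(0, 1\\)")
})

test_that("combination index reproduces the published per-level values", {
  ex <- amylase_example()
  for (pair in names(ex$mixtures)) {
    ref <- ex$reference[ex$reference$pair == pair, ]
    fits <- ex$fits[c(ref$agent_a[1], ref$agent_b[1])]
    met <- combination_index(ex$mixtures[[pair]], fits[[1]], fits[[2]])
    expect_equal(met$ci, ref$ci_printed, tolerance = 0.015)
    expect_equal(met$interaction_class,
                 ifelse(ref$ci_printed < 1, "synergism", "antagonism"))
  }
  # a single agent given at its own equi-effective dose is exactly additive
  ica <- dose_for_effect(acarbose_fit(), 0.4)
  met1 <- combination_index(data.frame(c_a = ica, c_b = 0, fa = 0.4),
                            acarbose_fit(), propolis_fit())
  expect_equal(met1$ci, 1, tolerance = 1e-12)
  expect_true(is.infinite(met1$dri_b))
})

test_that("CI = 1/DRI_A + 1/DRI_B holds as an identity", {
  ex <- amylase_example()
  withr::with_seed(3, extra <- data.frame(
    c_a = runif(20, 0.001, 0.4), c_b = runif(20, 0.01, 50),
    fa = runif(20, 0.05, 0.95)))
  for (obs in c(ex$mixtures, list(extra))) {
    met <- combination_index(obs, acarbose_fit(), propolis_fit())
    expect_equal(met$ci, 1 / met$dri_a + 1 / met$dri_b, tolerance = 1e-9)
  }
})

test_that("dose reduction index matches the published fold reductions", {
  # propolis in the fa = 0.235 mixture, nominal design dose (its IC10)
  c_b <- dose_for_effect(propolis_fit(), 0.10)
  expect_equal(dose_reduction_index(c_b, 0.235, propolis_fit()), 7.28,
               tolerance = 2e-3)
  # acarbose in the fa = 0.26 mixture
  c_a <- dose_for_effect(acarbose_fit(), 0.10)
  expect_equal(dose_reduction_index(c_a, 0.26, acarbose_fit()), 2.39,
               tolerance = 2e-3)
  # a component at its solitary equi-effective dose gains nothing
  expect_equal(dose_reduction_index(dose_for_effect(acarbose_fit(), 0.3),
                                    0.3, acarbose_fit()), 1)
  expect_error(dose_reduction_index(0, 0.3, acarbose_fit()), "> 0")
  expect_equal(dose_reduction_index(0, 0.3, acarbose_fit(), allow_infinite = TRUE),
               Inf)
})

test_that("CI is invariant under independent dose-unit rescaling", {
  obs <- data.frame(c_a = 0.0115, c_b = 0.0146, fa = 0.235)
  base <- combination_index(obs, acarbose_fit(), propolis_fit())$ci
  for (k in c(1e-3, 7, 1e4)) {
    fa_scaled <- median_effect_fit(0.061 * k, 1.32)
    obs_a <- transform(obs, c_a = c_a * k)
    expect_equal(combination_index(obs_a, fa_scaled, propolis_fit())$ci, base,
                 tolerance = 1e-12)
    fb_scaled <- median_effect_fit(1.07 * k, 0.512)
    obs_b <- transform(obs, c_b = c_b * k)
    expect_equal(combination_index(obs_b, acarbose_fit(), fb_scaled)$ci, base,
                 tolerance = 1e-12)
  }
})

test_that("a drug combined with itself is additive at every level", {
  fit <- kaempferol_fit()
  for (split in c(0, 0.25, 0.5, 0.9, 1)) {
    fa_levels <- c(0.1, 0.3, 0.5, 0.7, 0.9)
    total <- dose_for_effect(fit, fa_levels)
    obs <- data.frame(c_a = total * split, c_b = total * (1 - split),
                      fa = fa_levels)
    met <- combination_index(obs, fit, fit)
    expect_equal(met$ci, rep(1, 5), tolerance = 1e-12)
  }
})

test_that("CI classification follows the strict rule with an optional band", {
  expect_equal(classify_interaction(0.601), "synergism")
  expect_equal(classify_interaction(1.71), "antagonism")
  expect_equal(classify_interaction(1.0), "additivity")
  expect_equal(classify_interaction(c(0.99, 1.01), tolerance = 0.05),
               c("additivity", "additivity"))
  expect_error(classify_interaction(0), "> 0")
  expect_error(classify_interaction(-1), "> 0")
})

test_that("fa-CI curve supports observation and constant-ratio modes", {
  ex <- amylase_example()
  obs <- ex$mixtures$`acarbose+propolis`
  crv <- fa_ci_curve(ex$fits$acarbose, ex$fits$propolis, observations = obs)
  ref <- ex$reference[ex$reference$pair == "acarbose+propolis", ]
  expect_equal(crv$ci, ref$ci_printed, tolerance = 0.015)
  # a single observation agrees with combination_index
  one <- fa_ci_curve(ex$fits$acarbose, ex$fits$propolis,
                     observations = obs[2, ])
  expect_equal(one$ci,
               combination_index(obs[2, ], ex$fits$acarbose, ex$fits$propolis)$ci)
  # sham constant-ratio combination: CI = 1 along the whole curve
  fit <- acarbose_fit()
  sham <- fa_ci_curve(fit, fit, combo_fit = fit, ratio = 0.3)
  expect_equal(sham$ci, rep(1, nrow(sham)), tolerance = 1e-12)
  expect_error(fa_ci_curve(fit, fit), "observation mode.*constant-ratio")
})

test_that("isobologram coordinates sum to CI and label line position", {
  ex <- amylase_example()
  obs <- ex$mixtures$`acarbose+propolis`
  iso <- isobologram(ex$fits$acarbose, ex$fits$propolis, obs)
  expect_equal(iso$points$x + iso$points$y, iso$points$ci, tolerance = 1e-12)
  # synergistic levels fall below the additive line, the 90% level above it
  expect_equal(iso$points$position, c(rep("below", 4), "above"))
  # classical additive-line endpoints are the single-agent IC_x values
  expect_equal(iso$classical$ic_a, dose_for_effect(ex$fits$acarbose, iso$classical$level))
  expect_equal(iso$classical$ic_b, dose_for_effect(ex$fits$propolis, iso$classical$level))
  # plot builders return ggplot objects without evaluating data eagerly
  expect_s3_class(plot_isobologram(iso), "ggplot")
  expect_s3_class(plot_fa_ci(fa_ci_curve(ex$fits$acarbose, ex$fits$propolis,
                                         observations = obs)), "ggplot")
})

test_that("mixture median-effect fit on total dose matches the published row", {
  ex <- amylase_example()
  fit <- combination_median_effect(ex$mixtures$`acarbose+kaempferol`,
                                   unit_a = "mM", unit_b = "mM", agent = "A+K")
  expect_equal(fit$dm, 2.01, tolerance = 0.02)
  expect_equal(fit$m, 0.935, tolerance = 0.02)
  expect_equal(round(fit$r, 2), 0.99)
  expect_equal(fit$dose_unit, "mM")

  # heterogeneous units: composite label plus a warning, math unchanged
  expect_warning(
    fitp <- combination_median_effect(ex$mixtures$`acarbose+propolis`,
                                      unit_a = "mM", unit_b = "mg/mL"),
    "heterogeneous units")
  expect_equal(fitp$dose_unit, "mM+mg/mL")

  # a drug mixed with itself reproduces its own fit
  fitk <- kaempferol_fit()
  lv <- c(0.2, 0.4, 0.6, 0.8)
  tot <- dose_for_effect(fitk, lv)
  self <- combination_median_effect(
    data.frame(c_a = 0.7 * tot, c_b = 0.3 * tot, fa = lv))
  expect_equal(self$dm, fitk$dm, tolerance = 1e-9)
  expect_equal(self$m, fitk$m, tolerance = 1e-9)

  # two observations give an exact line
  two <- suppressWarnings(combination_median_effect(
    data.frame(c_a = c(0.5, 2), c_b = c(0.5, 2), fa = c(0.25, 0.75))))
  expect_equal(two$r, 1, tolerance = 1e-12)
})
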