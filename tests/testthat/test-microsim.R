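test_that("parameter draws follow the equation sampling distributions", {
  ch <- table3_parameters()

  # zero vcov: the draw is the point estimate
  ch0 <- ch
  for (o in names(ch0$equations))
    ch0$equations[[o]]$vcov[] <- 0
  expect_identical(sample_parameters(ch0),
                   lapply(ch0$equations, `[[`, "coef"))

  # fixed RNG state: identical draw
  set.seed(1); d1 <- sample_parameters(ch)
  set.seed(1); d2 <- sample_parameters(ch)
  expect_identical(d1, d2)

  # the spread of the income coefficient matches its published SE
  set.seed(2)
  draws <- replicate(4000, sample_parameters(ch)$bmi120[["ehii"]])
  se <- (-0.12 - (-1.58)) / (2 * qnorm(0.975))
  expect_lt(abs(sd(draws) - se) / se, 0.05)
  expect_lt(abs(mean(draws) - (-0.85)), 0.02)
})

test_that("the noise-free chain equals an independent arithmetic cascade", {
  ch <- table3_parameters()
  kid <- mean_child()
  got <- unlist(simulate_chain(kid, ch, ehii = "baseline",
                               residual_noise = FALSE))
  want <- cascade_oracle(ch, ehii = 7.02, sex = 0.516, mother_age = 33.6,
                         mother_foreign = 0.168)
  expect_equal(got, want, tolerance = 1e-12)

  # intercept-only chain: every child receives the intercept cascade
  ch0 <- noiseless_chain()
  for (o in names(ch0$equations)) {
    b <- ch0$equations[[o]]$coef
    b[setdiff(names(b), "(Intercept)")] <- 0
    ch0$equations[[o]]$coef <- b
  }
  kids <- data.frame(sex = c(0, 1), mother_age = c(25, 40),
                     mother_foreign = c(0, 1), ehii_baseline = c(6, 8))
  tr <- simulate_chain(kids, ch0, ehii = "baseline", residual_noise = FALSE)
  for (o in names(tr))
    expect_equal(tr[[o]],
                 rep(ch0$equations[[o]]$coef[["(Intercept)"]], 2))

  # a +0.1 income perturbation shifts the mean by 0.1 x gradient
  kids2 <- synthetic_cohort(50, seed = 3)
  kids2$ehii_baseline <- kids2$ehii
  t0 <- simulate_chain(kids2, ch, ehii = kids2$ehii, residual_noise = FALSE)
  t1 <- simulate_chain(kids2, ch, ehii = kids2$ehii + 0.1,
                       residual_noise = FALSE)
  expect_equal(mean(t1$bmi120) - mean(t0$bmi120),
               0.1 * income_effect_gradient(ch, "bmi120"),
               tolerance = 1e-10)
})

test_that("intercept calibration reaches its benchmarks and is idempotent", {
  ch <- table3_parameters()
  pop <- generate_population(1500, seed = 31)
  children <- expand_children(pop, 3000)
  d <- data.frame(ehii = children$ehii_baseline, sex = children$sex,
                  mother_age = children$mother_age,
                  mother_foreign = children$mother_foreign)

  cal <- calibrate_intercepts(ch, children)
  # only the first two intercepts move
  for (o in c("wt6", "wt18", "bmi48", "bmi84", "bmi120"))
    expect_identical(cal$equations[[o]]$coef, ch$equations[[o]]$coef)
  expect_equal(cal$equations$ga$coef[-1], ch$equations$ga$coef[-1])

  # implied premature prevalence and mean birth weight hit the targets
  tr <- simulate_chain(children, cal, ehii = "baseline",
                       residual_noise = FALSE)
  prem <- mean(pnorm((37 - tr$ga) / cal$equations$ga$residual_sd))
  expect_lt(abs(prem - calibration_targets()$premature_prevalence), 1e-4)
  expect_lt(abs(mean(tr$bw) * 100 - 3218), 10)  # grams

  # fixed point: recalibrating a calibrated chain moves nothing
  cal2 <- calibrate_intercepts(cal, children)
  expect_lt(abs(cal2$equations$ga$coef[["(Intercept)"]] -
                  cal$equations$ga$coef[["(Intercept)"]]), 1e-3)
  expect_lt(abs(cal2$equations$bw$coef[["(Intercept)"]] -
                  cal$equations$bw$coef[["(Intercept)"]]), 1e-3)

  # raising the birth-weight target by 100 g lifts alpha_2 by 1 hectogram
  t2 <- calibration_targets(mean_birth_weight_g = 3318)
  cal3 <- calibrate_intercepts(ch, children, targets = t2)
  expect_equal(cal3$equations$bw$coef[["(Intercept)"]] -
                 cal$equations$bw$coef[["(Intercept)"]], 1.0,
               tolerance = 1e-3)
})

test_that("IOTF classification is inclusive at the cut-offs", {
  cuts <- iotf_cutoffs()
  expect_true(all(cuts$overweight < cuts$obesity))

  expect_equal(as.character(classify_iotf(15.0, 120, "male")), "normal")
  expect_equal(as.character(classify_iotf(25.0, 120, "male")), "obese")
  expect_equal(as.character(classify_iotf(25.0, 120, 0)), "obese")

  ow_cut <- cuts$overweight[cuts$age_months == 84 & cuts$sex == "female"]
  ob_cut <- cuts$obesity[cuts$age_months == 84 & cuts$sex == "female"]
  expect_equal(as.character(classify_iotf(ow_cut, 84, "female")),
               "overweight")
  expect_equal(as.character(classify_iotf(ob_cut, 84, "female")), "obese")
  expect_equal(as.character(classify_iotf(ow_cut - 1e-9, 84, "female")),
               "normal")

  expect_error(classify_iotf(18, 60, "male"), "not in the cut-off table")
})

test_that("the experiment pairs runs across scenarios exactly", {
  pop <- generate_population(1000, seed = 41)
  children <- expand_children(pop, 2500)
  ch <- calibrate_intercepts(table3_parameters(), children)
  sc <- builtin_scenarios()
  ehii <- list(BS = children$ehii_baseline,
               BS_again = children$ehii_baseline,
               BI2 = scenario_ehii(children,
                                   apply_policy(pop, sc$BI2))$ehii_scenario)
  ex <- run_experiment(children, ehii, ch, n_runs = 20, master_seed = 5)

  # identical EHII under common random numbers: identical prevalences
  expect_identical(ex$prevalence[, "BS", , ], ex$prevalence[, "BS_again", , ])
  pr <- prevalence_ratio(ex, "BS_again", "BS", 120, "overweight")
  expect_identical(pr$runs, rep(1, 20))
  expect_equal(pr$point, 1)

  # reproducibility of the whole experiment
  ex2 <- run_experiment(children, ehii, ch, n_runs = 20, master_seed = 5)
  expect_identical(ex$prevalence, ex2$prevalence)

  # with parameters fixed at the point estimates (all BMI income gradients
  # negative) a universal monthly benefit lowers prevalence in every run
  ch0 <- ch
  for (o in names(ch0$equations)) ch0$equations[[o]]$vcov[] <- 0
  ex0 <- run_experiment(children, ehii, ch0, n_runs = 20, master_seed = 5)
  expect_true(all(ex0$prevalence[, "BI2", , ] <= ex0$prevalence[, "BS", , ]))
  # and on average also under full parameter uncertainty
  expect_true(all(apply(ex$prevalence[, "BI2", , ], c(2, 3), mean) <=
                    apply(ex$prevalence[, "BS", , ], c(2, 3), mean)))

  expect_error(run_experiment(children, ehii, ch, n_runs = 1), "n_runs")
})
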