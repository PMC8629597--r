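test_that("the built-in scenario set encodes the published rules", {
  sc <- builtin_scenarios()
  expect_named(sc, c("BS", "BI1", "BI2", "PR1", "PR2", "NB1", "NB2",
                     "CB1", "CB2"))
  expect_equal(sc$BS$amount, 0)
  expect_equal(sc$BI2[c("amount", "periodicity", "recipients", "basis")],
               list(amount = 100, periodicity = "monthly",
                    recipients = "all_members", basis = "none"))
  expect_equal(sc$CB2[c("amount", "periodicity", "age_limit", "threshold",
                        "basis")],
               list(amount = 500, periodicity = "monthly", age_limit = 5,
                    threshold = 500, basis = "equivalised"))
  expect_equal(sc$PR1$basis, "per_capita")
  expect_equal(sc$NB1$age_limit, 1)
})

test_that("eligibility uses a strict threshold on the configured basis", {
  hh4 <- make_household(1, c(40, 38, 10, 3), 1900)   # per capita 475
  hh_at <- make_household(2, c(40, 38, 10, 3), 2000) # per capita exactly 500
  pop <- make_pop(hh4, hh_at)
  hh <- households(pop)
  pr <- builtin_scenarios()$PR2
  expect_equal(is_eligible(hh, pr), c(TRUE, FALSE))
  expect_true(all(is_eligible(hh, builtin_scenarios()$BI1)))

  # equivalised basis: income 1900 over eq size 2.1 is 904.8, not eligible
  cb <- builtin_scenarios()$CB2
  expect_equal(is_eligible(hh, cb), c(FALSE, FALSE))
  poor <- make_household(3, c(40, 38, 10, 3), 1000)  # equivalised 476.2
  expect_equal(is_eligible(households(make_pop(poor)), cb), TRUE)
})

test_that("benefit amounts add up exactly per rule and periodicity", {
  hh <- make_household(1, c(40, 38, 3, 1), 1000)
  pop <- make_pop(hh)

  bi1 <- apply_policy(pop, builtin_scenarios()$BI1)
  expect_equal(unique(bi1$disposable_income), 1000 + 4 * 100 / 12)

  cb2 <- apply_policy(pop, builtin_scenarios()$CB2)  # eligible: eq 476.2
  expect_equal(unique(cb2$disposable_income), 1000 + 2 * 500)

  bs <- apply_policy(pop, builtin_scenarios()$BS)
  expect_equal(bs$disposable_income, pop$disposable_income)

  rich <- make_pop(make_household(1, c(40, 38, 3, 1), 5000))
  expect_equal(apply_policy(rich, builtin_scenarios()$CB2)$disposable_income,
               rich$disposable_income)
})

test_that("benefits never decrease income and monthly dominates yearly", {
  pop <- generate_population(800, seed = 21)
  sc <- builtin_scenarios()
  base <- pop$disposable_income
  for (s in sc) {
    cf <- apply_policy(pop, s)
    expect_true(all(cf$disposable_income >= base), label = s$name)
  }
  for (pair in list(c("BI1", "BI2"), c("PR1", "PR2"), c("NB1", "NB2"),
                    c("CB1", "CB2"))) {
    up_y <- apply_policy(pop, sc[[pair[1]]])$disposable_income - base
    up_m <- apply_policy(pop, sc[[pair[2]]])$disposable_income - base
    expect_true(all(up_m >= up_y), label = paste(pair, collapse = " vs "))
    expect_equal(up_m, up_y * 12)
  }
  # nesting: newborn benefit recipients are a subset of child benefit ones
  up_nb <- apply_policy(pop, sc$NB1)$disposable_income - base
  up_cb <- apply_policy(pop, sc$CB1)$disposable_income - base
  expect_true(all(up_cb >= up_nb))
})

test_that("annual cost scales with the represented population and amount", {
  pop <- generate_population(500, seed = 13)
  sc <- builtin_scenarios()

  # universal benefit of 100/year across 60M represented persons costs 6e9
  cost <- scenario_cost(pop, sc$BI1, national_persons = 60e6)
  expect_equal(cost$annual_cost, 6.0e9, tolerance = 1e-9)
  expect_equal(scenario_cost(pop, sc$BS)$annual_cost, 0)

  # linear in amount: monthly 100 costs 12x yearly 100
  c1 <- scenario_cost(pop, sc$BI1, population_scale = 1)$annual_cost
  c2 <- scenario_cost(pop, sc$BI2, population_scale = 1)$annual_cost
  expect_equal(c2, 12 * c1)

  # linear in weights at a fixed scale
  pop2 <- pop
  pop2$survey_weight <- 2 * pop$survey_weight
  expect_equal(scenario_cost(pop2, sc$PR2, population_scale = 1)$annual_cost,
               2 * scenario_cost(pop, sc$PR2, population_scale = 1)$annual_cost)

  # child benefit reaches at least the newborn benefit recipients
  expect_gte(scenario_cost(pop, sc$CB1, population_scale = 1)$annual_cost,
             scenario_cost(pop, sc$NB1, population_scale = 1)$annual_cost)

  expect_error(scenario_cost(pop, sc$BI1, population_scale = -1))
})

test_that("scenario EHII is the log counterfactual equivalised income", {
  poor <- make_household(1, c(40, 38, 3, 1), 1000)   # eq size 2.1, eq 476.2
  rich <- make_household(2, c(40, 38, 3), 5000)
  pop <- make_pop(poor, rich)
  children <- expand_children(pop, 3)
  cb2 <- builtin_scenarios()$CB2

  ch <- scenario_ehii(children, apply_policy(pop, cb2))
  # ineligible household: scenario EHII equals baseline
  i_rich <- ch$household_id == 2
  expect_equal(ch$ehii_scenario[i_rich], ch$ehii_baseline[i_rich])
  # eligible: equivalised uplift of 2 x 500 / 2.1 on top of 476.19
  i_poor <- ch$household_id == 1
  expect_equal(unique(ch$ehii_scenario[i_poor]),
               log(1000 / 2.1 + 1000 / 2.1))

  # universal monthly benefit lifts every household strictly
  bi2 <- scenario_ehii(children, apply_policy(pop, builtin_scenarios()$BI2))
  expect_true(all(bi2$ehii_scenario > bi2$ehii_baseline))
})
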