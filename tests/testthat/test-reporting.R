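# Minimal hand-built experiment object for ratio arithmetic.
fake_experiment <- function(prev_bs, prev_sc, scenario = "X") {
  n <- length(prev_bs)
  prev <- array(NA_real_, dim = c(n, 2, 3, 2),
                dimnames = list(NULL, c("BS", scenario),
                                c("48", "84", "120"),
                                c("overweight", "obesity")))
  for (a in c("48", "84", "120")) for (cat in c("overweight", "obesity")) {
    prev[, "BS", a, cat] <- prev_bs
    prev[, scenario, a, cat] <- prev_sc
  }
  structure(list(prevalence = prev, n_runs = n, n_children = NA_integer_,
                 master_seed = 0L, scenarios = c("BS", scenario),
                 overweight_includes_obese = TRUE),
            class = "scenario_experiment")
}

test_that("prevalence ratios are paired per run with percentile intervals", {
  ex <- fake_experiment(c(0.2, 0.25, 0.3), c(0.2, 0.25, 0.3))
  pr <- prevalence_ratio(ex, "X", "BS", 120, "overweight")
  expect_equal(pr$point, 1)
  expect_equal(c(pr$lower, pr$upper), c(1, 1))

  ex2 <- fake_experiment(c(0.2, 0.25, 0.3), c(0.1, 0.125, 0.15))
  pr2 <- prevalence_ratio(ex2, "X", "BS", 84, "obesity")
  expect_equal(pr2$point, 0.5)
  expect_equal(pr2$runs, rep(0.5, 3))

  ex0 <- fake_experiment(c(0.2, 0, 0.3), c(0.1, 0.1, 0.1))
  expect_error(prevalence_ratio(ex0, "X", "BS", 48, "obesity"), "zero")
})

test_that("the comparison table links PR, reduction and marginal cost", {
  ex <- fake_experiment(rep(0.25, 4), c(0.20, 0.18, 0.22, 0.20))
  comp <- comparison_table(ex, costs = c(X = 6.06e9))
  row <- comp[comp$age_months == 120 & comp$category == "overweight", ]
  expect_equal(row$pr, mean(c(0.20, 0.18, 0.22, 0.20) / 0.25))
  # internal consistency: reduction_pp = 100 x prev_baseline x (1 - PR)
  expect_equal(row$reduction_pp, 100 * row$prev_baseline * (1 - row$pr))
  expect_equal(row$marginal_cost, 6.06e9 / row$reduction_pp)
  expect_true(all(comp$pr_lower <= comp$pr & comp$pr <= comp$pr_upper))
})

test_that("marginal cost is the cost per percentage point, else NA", {
  expect_equal(marginal_cost(6.06e9, 0.31), 6.06e9 / 0.31)
  expect_true(is.na(marginal_cost(6.06e9, 0)))
  expect_true(is.na(marginal_cost(6.06e9, -0.2)))
  expect_equal(marginal_cost(2 * 6.06e9, 0.31), 2 * marginal_cost(6.06e9, 0.31))
  expect_equal(marginal_cost(c(1e9, 2e9), c(0.5, 0)), c(2e9, NA_real_))
})

test_that("kernel density summaries are normalised and accurate", {
  set.seed(8)
  x <- rnorm(10000)
  d <- density_summary(x)
  at0 <- d$density[which.min(abs(d$x))]
  expect_lt(abs(at0 - dnorm(0)), 0.02)
  # trapezoid integral over the default grid
  integral <- sum(diff(d$x) * (head(d$density, -1) + tail(d$density, -1)) / 2)
  expect_lt(abs(integral - 1), 1e-3)

  # weights shift mass as expected
  w <- ifelse(x > 0, 2, 1)
  dw <- density_summary(x, weights = w)
  expect_gt(sum(dw$density[dw$x > 0]), sum(dw$density[dw$x < 0]))

  expect_error(density_summary(rep(1, 200)), "degenerate")
  expect_error(density_summary(rnorm(10)), "100")
})

test_that("report bundles are reproducible and carry the seed", {
  pop <- generate_population(400, seed = 51)
  children <- expand_children(pop, 900)
  ch <- table3_parameters()
  ehii <- list(BS = children$ehii_baseline,
               BI2 = scenario_ehii(children,
                                   apply_policy(pop, builtin_scenarios()$BI2)
                                   )$ehii_scenario)
  ex <- run_experiment(children, ehii, ch, n_runs = 10, master_seed = 77)
  comp <- comparison_table(ex)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_report(ex, comp, file.path(d1, "rep"), config = list(note = "a"))
  write_report(ex, comp, file.path(d2, "rep"), config = list(note = "a"))
  for (f in c("comparison.csv", "per_run_prevalence.csv",
              "run_metadata.json")) {
    expect_true(file.exists(file.path(d1, "rep", f)))
    expect_identical(readLines(file.path(d1, "rep", f)),
                     readLines(file.path(d2, "rep", f)))
  }
  meta <- jsonlite::read_json(file.path(d1, "rep", "run_metadata.json"))
  expect_equal(meta$master_seed, 77)
  expect_equal(meta$n_runs, 10)

  # non-computable marginal costs appear as the NC sentinel
  comp$marginal_cost <- NA_real_
  write_report(ex, comp, file.path(d1, "nc"))
  got <- read.csv(file.path(d1, "nc", "comparison.csv"),
                  stringsAsFactors = FALSE)
  expect_true(all(got$marginal_cost == "NC"))
})
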