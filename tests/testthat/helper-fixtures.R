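# Hand-built person-level households for arithmetic tests.
make_household <- function(id, ages, income, weight = 1, sexes = NULL,
                           mother_age = 30, mother_foreign = 0) {
  n <- length(ages)
  if (is.null(sexes)) sexes <- c("female", rep("male", n - 1))
  data.frame(household_id = id, person_id = NA_integer_, age = ages,
             sex = sexes, is_mother = c(TRUE, rep(FALSE, n - 1)),
             disposable_income = income, survey_weight = weight,
             mother_age = mother_age, mother_foreign = mother_foreign,
             stringsAsFactors = FALSE)
}

make_pop <- function(...) {
  pop <- do.call(rbind, list(...))
  pop$person_id <- seq_len(nrow(pop))
  class(pop) <- c("silc_population", "data.frame")
  pop
}

# Chain with zero residual noise: outcomes are exact linear functions of
# their predecessors; used as an exact-recovery oracle.
noiseless_chain <- function() {
  ch <- table3_parameters(vcov = "diagonal")
  for (o in names(ch$equations)) ch$equations[[o]]$residual_sd <- 0
  ch
}

# Reference covariate means used in plug-through checks (survey column for
# income / foreign share, cohort column for the rest).
mean_child <- function() {
  data.frame(sex = 0.516, mother_age = 33.6, mother_foreign = 0.168,
             ehii_baseline = 7.02, weight = 1)
}

# Independent oracle: the conditional-mean cascade computed with plain
# arithmetic from a chain's point estimates (no use of simulate_chain).
cascade_oracle <- function(chain, ehii, sex, mother_age, mother_foreign) {
  cv <- c(ehii = ehii, mother_age = mother_age,
          mother_foreign = mother_foreign, sex = sex)
  vals <- c()
  for (o in c("ga", "bw", "wt6", "wt18", "bmi48", "bmi84", "bmi120")) {
    b <- chain$equations[[o]]$coef
    lag_terms <- setdiff(names(b), c("(Intercept)", names(cv)))
    vals[o] <- b[["(Intercept)"]] + sum(b[names(cv)] * cv) +
      sum(b[lag_terms] * vals[lag_terms])
  }
  vals
}
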