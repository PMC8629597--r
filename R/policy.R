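#' Declare a benefit policy scenario
#'
#' A scenario is a declarative benefit rule: who is eligible (an income
#' threshold on a per-capita or equivalised basis, or no test), how much is
#' paid per payment, how often, and to whom (all household members or each
#' child under an age cut). Benefits only ever add income.
#'
#' @param name Scenario label (e.g. `"CB2"`).
#' @param amount Benefit amount in euros per payment (>= 0).
#' @param periodicity `"yearly"` or `"monthly"`. A yearly payment is spread
#'   uniformly (amount/12) in the monthly income accounting.
#' @param recipients `"all_members"` or `"children_under"`.
#' @param age_limit Age cut in years for `recipients = "children_under"`
#'   (strict: a child aged exactly `age_limit` is not a recipient).
#' @param threshold Eligibility income threshold in euros/month (strict
#'   `<`), or `NULL` when `basis = "none"`.
#' @param basis `"none"`, `"per_capita"` (income / household size) or
#'   `"equivalised"` (income / OECD-modified size).
#' @return An object of class `policy_scenario`.
#' @seealso [builtin_scenarios()] for the standard nine-scenario set.
#' @export
policy_scenario <- function(name, amount = 0,
                            periodicity = c("yearly", "monthly"),
                            recipients = c("all_members", "children_under"),
                            age_limit = NULL, threshold = NULL,
                            basis = c("none", "per_capita", "equivalised")) {
  periodicity <- match.arg(periodicity)
  recipients  <- match.arg(recipients)
  basis       <- match.arg(basis)
  if (amount < 0) stop("'amount' must be >= 0")
  if (basis != "none" && (is.null(threshold) || threshold <= 0))
    stop("'threshold' must be > 0 when an eligibility basis is set")
  if (recipients == "children_under" &&
      (is.null(age_limit) || age_limit <= 0))
    stop("'age_limit' must be > 0 for child-targeted recipients")
  structure(list(name = name, amount = amount, periodicity = periodicity,
                 recipients = recipients, age_limit = age_limit,
                 threshold = threshold, basis = basis),
            class = "policy_scenario")
}

#' @export
print.policy_scenario <- function(x, ...) {
  elig <- if (x$basis == "none") "all households" else
    sprintf("%s income < €%g/month", gsub("_", "-", x$basis), x$threshold)
  rec <- if (x$recipients == "all_members") "all household members" else
    sprintf("every child < %g years", x$age_limit)
  cat(sprintf("<policy_scenario> %s: €%g %s to %s; eligibility: %s\n",
              x$name, x$amount, x$periodicity, rec, elig))
  invisible(x)
}

#' The built-in scenario set
#'
#' Baseline (BS, a zero-amount no-op) plus eight benefit reforms in pairs
#' with yearly/monthly intensity:
#' \describe{
#'   \item{BI1/BI2}{basic income, 100 euros yearly/monthly to every household
#'     member, no eligibility test.}
#'   \item{PR1/PR2}{poverty reduction, 100 euros yearly/monthly per member of
#'     households with per-capita income below 500 euros/month.}
#'   \item{NB1/NB2}{new-borns benefit, 500 euros yearly/monthly per child
#'     under 1 year in households with equivalised income below 500
#'     euros/month.}
#'   \item{CB1/CB2}{child benefit, as NB but per child under 5 years.}
#' }
#' The income basis of the targeted thresholds (per-capita for PR,
#' equivalised for NB/CB) follows the policy definitions used here; both can
#' be overridden by constructing scenarios with [policy_scenario()].
#'
#' @return Named list of `policy_scenario` objects.
#' @export
builtin_scenarios <- function() {
  list(
    BS  = policy_scenario("BS", 0, "yearly", "all_members", basis = "none"),
    BI1 = policy_scenario("BI1", 100, "yearly",  "all_members", basis = "none"),
    BI2 = policy_scenario("BI2", 100, "monthly", "all_members", basis = "none"),
    PR1 = policy_scenario("PR1", 100, "yearly",  "all_members",
                          threshold = 500, basis = "per_capita"),
    PR2 = policy_scenario("PR2", 100, "monthly", "all_members",
                          threshold = 500, basis = "per_capita"),
    NB1 = policy_scenario("NB1", 500, "yearly",  "children_under",
                          age_limit = 1, threshold = 500, basis = "equivalised"),
    NB2 = policy_scenario("NB2", 500, "monthly", "children_under",
                          age_limit = 1, threshold = 500, basis = "equivalised"),
    CB1 = policy_scenario("CB1", 500, "yearly",  "children_under",
                          age_limit = 5, threshold = 500, basis = "equivalised"),
    CB2 = policy_scenario("CB2", 500, "monthly", "children_under",
                          age_limit = 5, threshold = 500, basis = "equivalised")
  )
}

#' Household eligibility under a scenario
#'
#' Strict-inequality income test on the scenario's basis: a household with
#' per-capita (or equivalised) income exactly at the threshold is not
#' eligible. With `basis = "none"` every household is eligible.
#'
#' @param hh Household table from [households()].
#' @param scenario A `policy_scenario`.
#' @return Logical vector, one element per household.
#' @export
is_eligible <- function(hh, scenario) {
  switch(scenario$basis,
    none        = rep(TRUE, nrow(hh)),
    per_capita  = hh$per_capita_income < scenario$threshold,
    equivalised = hh$eq_income < scenario$threshold
  )
}

recipient_count <- function(pop, hh, scenario) {
  if (scenario$recipients == "all_members") return(hh$size)
  f <- factor(pop$household_id, levels = unique(pop$household_id))
  as.vector(tapply(pop$age < scenario$age_limit, f, sum))
}

#' Apply a benefit scenario to baseline incomes
#'
#' Eligibility is assessed once on the (baseline) incomes in `pop`; eligible
#' households receive `monthly_amount x n_recipients` added to disposable
#' income, where a yearly benefit contributes `amount / 12` per month.
#' Ineligible households are unchanged; income never decreases.
#'
#' @param pop Person-level baseline population.
#' @param scenario A `policy_scenario`.
#' @return The population with counterfactual `disposable_income`.
#' @examples
#' pop <- generate_population(50, seed = 1)
#' cf <- apply_policy(pop, builtin_scenarios()$BI2)
#' all(cf$disposable_income >= pop$disposable_income)
#' @export
apply_policy <- function(pop, scenario) {
  hh <- households(pop)
  elig <- is_eligible(hh, scenario)
  nrec <- recipient_count(pop, hh, scenario)
  monthly <- if (scenario$periodicity == "monthly") scenario$amount
             else scenario$amount / 12
  uplift <- ifelse(elig, monthly * nrec, 0)
  pop$disposable_income <- pop$disposable_income +
    uplift[match(pop$household_id, hh$household_id)]
  pop
}

#' National annual cost of a scenario
#'
#' Sums `survey_weight x population_scale x yearly_amount x n_recipients`
#' over eligible households, where a monthly benefit costs `12 x amount` per
#' recipient per year. By default `population_scale` is chosen so that the
#' person-weighted sample represents `national_persons` residents.
#'
#' @param pop Person-level baseline population.
#' @param scenario A `policy_scenario`.
#' @param population_scale Multiplier from sample weights to national
#'   totals; if `NULL`, computed as `national_persons / sum(person weights)`.
#' @param national_persons National resident population represented by the
#'   weighted sample (default 60.6 million).
#' @return A `cost_report` list: `scenario`, `annual_cost` (euros/year),
#'   `n_recipient_units` (weight-scaled recipients), `delta_vs_baseline`
#'   (equal to `annual_cost`; the baseline costs nothing).
#' @export
scenario_cost <- function(pop, scenario, population_scale = NULL,
                          national_persons = 60.6e6) {
  if (!is.null(population_scale) && population_scale < 0)
    stop("'population_scale' must be >= 0")
  hh <- households(pop)
  if (is.null(population_scale))
    population_scale <- national_persons / sum(pop$survey_weight)
  elig <- is_eligible(hh, scenario)
  nrec <- recipient_count(pop, hh, scenario)
  yearly <- if (scenario$periodicity == "monthly") 12 * scenario$amount
            else scenario$amount
  cost <- sum(hh$survey_weight[elig] * population_scale * yearly * nrec[elig])
  structure(list(scenario = scenario$name, annual_cost = cost,
                 n_recipient_units = sum(hh$survey_weight[elig] *
                                           population_scale * nrec[elig]),
                 delta_vs_baseline = cost),
            class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf("<cost_report> %s: €%.3g/year over %.3g recipient units\n",
              x$scenario, x$annual_cost, x$n_recipient_units))
  invisible(x)
}

#' Scenario EHII for the child study population
#'
#' Fills `ehii_scenario` = log counterfactual equivalised income, looked up
#' from the household table of a population returned by [apply_policy()].
#' Because benefits only add income, `ehii_scenario >= ehii_baseline`.
#'
#' @param children Child population from [expand_children()].
#' @param pop_counterfactual Person-level population after [apply_policy()].
#' @return `children` with an `ehii_scenario` column.
#' @export
scenario_ehii <- function(children, pop_counterfactual) {
  hh <- households(pop_counterfactual)
  m <- match(children$household_id, hh$household_id)
  if (any(is.na(m))) stop("children reference households not in the population")
  eq <- hh$eq_income[m]
  if (any(eq <= 0)) stop("non-positive counterfactual equivalised income")
  children$ehii_scenario <- log(eq)
  children
}
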