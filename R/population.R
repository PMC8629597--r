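#' Default parameters for the synthetic household population
#'
#' The generator emulates the structure of an EU-SILC-style household survey
#' restricted to families with young children: 1-2 adults, 1-3 children, a
#' log-normal equivalised income, and maternal covariates. Income defaults
#' (log mean 7.02, log sd 0.67, euros/month), the female share (51.6\%),
#' maternal age (33.6 [5.2] years at delivery) and the foreign-mother
#' fraction (16.8\%) reproduce the marginal statistics of the Italian
#' survey population the model is built around.
#'
#' Income is drawn at the *equivalised* level and multiplied back up to the
#' household level, so the generated log equivalised income hits the target
#' mean/sd by construction regardless of household composition.
#'
#' @return Named list of generator parameters:
#' \describe{
#'   \item{log_income_mean, log_income_sd}{mean/sd of log equivalised
#'     disposable income (euros/month per consumption unit).}
#'   \item{p_second_adult}{probability a household has a second adult.}
#'   \item{child_count_probs}{probabilities of 1, 2, 3 children.}
#'   \item{child_age_max}{maximum child age in years (integer).}
#'   \item{p_female_child}{probability a child is female.}
#'   \item{mother_age_mean, mother_age_sd, mother_age_range}{maternal age at
#'     delivery (years), normal draw truncated to the range.}
#'   \item{p_mother_foreign}{probability the mother was born abroad.}
#'   \item{weight_sdlog}{log-sd of the log-normal survey weights.}
#' }
#' @export
population_defaults <- function() {
  list(
    log_income_mean   = 7.02,
    log_income_sd     = 0.67,
    p_second_adult    = 0.8,
    child_count_probs = c(0.4, 0.4, 0.2),
    child_age_max     = 13L,
    p_female_child    = 0.516,
    mother_age_mean   = 33.6,
    mother_age_sd     = 5.2,
    mother_age_range  = c(16, 50),
    p_mother_foreign  = 0.168,
    weight_sdlog      = 0.5
  )
}

#' Generate a synthetic survey-like household population
#'
#' Draws households with 1-2 adults and 1-3 children (at least one child
#' under 5, imposed at generation time so the population satisfies the
#' standard sample restriction), a log-normal equivalised disposable income,
#' survey weights, and maternal covariates. The result is a person-level
#' table with household-level fields repeated on each member row, the usual
#' layout of survey microdata.
#'
#' @param n_households Number of households to generate (positive integer).
#' @param params Generator parameters, see [population_defaults()]. A partial
#'   list is merged over the defaults.
#' @param seed Optional integer seed; a fixed seed makes the population
#'   bitwise reproducible.
#' @return A `data.frame` of class `silc_population`, one row per person,
#'   with columns `household_id`, `person_id`, `age` (integer years), `sex`
#'   (`"male"`/`"female"`), `is_mother`, `disposable_income` (household
#'   total, euros/month), `survey_weight`, `mother_age` (age at delivery),
#'   `mother_foreign` (0 = Italy, 1 = other).
#' @examples
#' pop <- generate_population(100, seed = 1)
#' head(households(pop))
#' @export
generate_population <- function(n_households, params = list(), seed = NULL) {
  if (length(n_households) != 1 || is.na(n_households) || n_households < 1)
    stop("'n_households' must be a positive integer")
  p <- modifyList(population_defaults(), params)
  if (p$log_income_sd < 0) stop("'log_income_sd' must be >= 0")
  if (any(p$child_count_probs < 0) || sum(p$child_count_probs) <= 0)
    stop("'child_count_probs' must be non-negative and sum to > 0")
  if (!is.null(seed)) set.seed(seed)

  n <- as.integer(n_households)
  n_child    <- sample.int(length(p$child_count_probs), n, replace = TRUE,
                           prob = p$child_count_probs)
  second     <- runif(n) < p$p_second_adult
  mother_age <- pmin(pmax(rnorm(n, p$mother_age_mean, p$mother_age_sd),
                          p$mother_age_range[1]), p$mother_age_range[2])
  foreign    <- as.integer(runif(n) < p$p_mother_foreign)
  eq_income  <- exp(rnorm(n, p$log_income_mean, p$log_income_sd))
  svy_weight <- rlnorm(n, 0, p$weight_sdlog)

  child_ages <- lapply(n_child, function(k) {
    a <- sample.int(p$child_age_max + 1L, k, replace = TRUE) - 1L
    # at least one child under 5 (sample-restriction structure by design)
    if (all(a >= 5L)) a[1L] <- sample.int(5L, 1L) - 1L
    a
  })
  child_sex <- lapply(n_child, function(k) {
    ifelse(runif(k) < p$p_female_child, "female", "male")
  })

  # current mother age = age at delivery of the oldest child + that child's age
  mother_now  <- as.integer(round(mother_age)) + vapply(child_ages, max, 0L)
  partner_age <- mother_now + 2L

  ages <- Map(function(i) {
    c(mother_now[i], if (second[i]) partner_age[i], child_ages[[i]])
  }, seq_len(n))
  sexes <- Map(function(i) {
    c("female", if (second[i]) "male", child_sex[[i]])
  }, seq_len(n))
  hh_size <- lengths(ages)

  eq_size <- vapply(ages, equivalised_size, 0)
  disposable_income <- eq_income * eq_size

  hid <- rep(seq_len(n), hh_size)
  pop <- data.frame(
    household_id      = hid,
    person_id         = seq_len(sum(hh_size)),
    age               = unlist(ages),
    sex               = unlist(sexes),
    is_mother         = unlist(Map(function(k) c(TRUE, rep(FALSE, k - 1L)),
                                   hh_size)),
    disposable_income = disposable_income[hid],
    survey_weight     = svy_weight[hid],
    mother_age        = mother_age[hid],
    mother_foreign    = foreign[hid],
    stringsAsFactors  = FALSE
  )
  class(pop) <- c("silc_population", "data.frame")
  pop
}

#' OECD-modified equivalised household size
#'
#' Consumption units of a household: 1.0 for the first adult (member aged
#' 14 or over), 0.5 for each additional member aged 14+, and 0.3 for each
#' member under 14. If a household has no member aged 14+ the first member
#' counts as the head (1.0).
#'
#' @param ages Numeric vector of member ages in years (one household).
#' @return Equivalised size (positive scalar).
#' @examples
#' equivalised_size(c(35, 33, 3))      # 1.8
#' equivalised_size(c(35, 33, 3, 1))   # 2.1
#' @export
equivalised_size <- function(ages) {
  if (length(ages) == 0) stop("empty household")
  if (any(is.na(ages)) || any(ages < 0)) stop("ages must be non-negative")
  n_adult <- sum(ages >= 14)
  n_young <- sum(ages < 14)
  if (n_adult > 0) 1 + 0.5 * (n_adult - 1) + 0.3 * n_young
  else 1 + 0.3 * (n_young - 1)
}

#' Equivalised household income
#'
#' Household disposable income divided by the OECD-modified equivalised size.
#'
#' @param income Household disposable income (euros/month, >= 0).
#' @param ages Member ages of the household.
#' @return Income per consumption unit (euros/month).
#' @export
equivalise_income <- function(income, ages) {
  if (income < 0) stop("income must be >= 0")
  income / equivalised_size(ages)
}

#' Aggregate a person-level population to a household table
#'
#' @param pop Person-level population as from [generate_population()].
#' @return One row per household: `household_id`, `size`, `eq_size`
#'   (OECD-modified), `disposable_income`, `eq_income`
#'   (= income / eq_size), `per_capita_income` (= income / size),
#'   `survey_weight`, `mother_age`, `mother_foreign`, `n_under1`,
#'   `n_under5`, `n_under14`.
#' @export
households <- function(pop) {
  f <- factor(pop$household_id, levels = unique(pop$household_id))
  n14  <- as.vector(tapply(pop$age >= 14, f, sum))
  nlt  <- as.vector(tapply(pop$age < 14, f, sum))
  eq_size <- ifelse(n14 > 0, 1 + 0.5 * (n14 - 1) + 0.3 * nlt,
                    1 + 0.3 * (nlt - 1))
  first <- !duplicated(pop$household_id)
  hh <- data.frame(
    household_id      = pop$household_id[first],
    size              = as.vector(tapply(rep(1L, nrow(pop)), f, sum)),
    eq_size           = eq_size,
    disposable_income = pop$disposable_income[first],
    survey_weight     = pop$survey_weight[first],
    mother_age        = pop$mother_age[first],
    mother_foreign    = pop$mother_foreign[first],
    n_under1          = as.vector(tapply(pop$age < 1, f, sum)),
    n_under5          = as.vector(tapply(pop$age < 5, f, sum)),
    n_under14         = nlt,
    stringsAsFactors  = FALSE
  )
  hh$eq_income         <- hh$disposable_income / hh$eq_size
  hh$per_capita_income <- hh$disposable_income / hh$size
  hh
}

#' Apply the standard sample restrictions
#'
#' Retains households with at most `max_size` members and at least one
#' member younger than `require_child_under` years. The operation is
#' idempotent.
#'
#' @param pop Person-level population.
#' @param max_size Maximum household size (default 7).
#' @param require_child_under Age cut in years a household must have a child
#'   below (default 5).
#' @return The restricted person-level population.
#' @export
apply_sample_restrictions <- function(pop, max_size = 7,
                                      require_child_under = 5) {
  hh <- households(pop)
  f <- factor(pop$household_id, levels = unique(pop$household_id))
  n_req <- as.vector(tapply(pop$age < require_child_under, f, sum))
  keep <- hh$household_id[hh$size <= max_size & n_req > 0]
  out <- pop[pop$household_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("silc_population", "data.frame")
  out
}

#' Largest-remainder apportionment
#'
#' Allocates `total` integer units proportionally to `weights`, flooring the
#' exact quotas and distributing the remainder to the largest fractional
#' parts (ties broken by position). Conserves `total` exactly and is
#' deterministic.
#'
#' @param weights Positive weights.
#' @param total Non-negative integer total to allocate.
#' @return Integer vector of counts summing to `total`.
#' @export
largest_remainder <- function(weights, total) {
  if (any(weights <= 0)) stop("weights must be positive")
  if (total < 0) stop("total must be >= 0")
  q <- weights / sum(weights) * total
  b <- floor(q)
  r <- as.integer(round(total - sum(b)))
  if (r > 0) {
    o <- order(-(q - b), seq_along(q))
    b[o[seq_len(r)]] <- b[o[seq_len(r)]] + 1
  }
  as.integer(b)
}

#' Expand children under 5 to a weighted study population
#'
#' Selects every household member younger than 5 and replicates each child
#' proportionally to the household survey weight (largest-remainder
#' rounding), producing exactly `target_n` child records, each with weight 1.
#' Each record carries the child's own sex (0 = male, 1 = female), maternal
#' covariates, and `ehii_baseline` = log equivalised household income.
#'
#' @param pop Person-level population (after sample restrictions).
#' @param target_n Total number of child records to produce; must be at
#'   least the number of distinct children under 5. Default 30910.
#' @return A `data.frame` of class `child_population` with columns
#'   `child_id`, `household_id`, `source_person_id`, `sex`, `mother_age`,
#'   `mother_foreign`, `ehii_baseline`, `weight`.
#' @export
expand_children <- function(pop, target_n = 30910) {
  hh <- households(pop)
  kids <- pop[pop$age < 5, , drop = FALSE]
  if (nrow(kids) == 0) stop("no children under 5 in the population")
  if (any(hh$survey_weight <= 0)) stop("survey weights must be positive")
  if (target_n < nrow(kids))
    stop("'target_n' is smaller than the number of distinct children")
  m <- match(kids$household_id, hh$household_id)
  counts <- largest_remainder(kids$survey_weight, target_n)
  idx <- rep(seq_len(nrow(kids)), counts)
  out <- data.frame(
    child_id         = seq_len(target_n),
    household_id     = kids$household_id[idx],
    source_person_id = kids$person_id[idx],
    sex              = as.integer(kids$sex[idx] == "female"),
    mother_age       = kids$mother_age[idx],
    mother_foreign   = kids$mother_foreign[idx],
    ehii_baseline    = log(hh$eq_income[m])[idx],
    weight           = 1,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(out$ehii_baseline)))
    stop("non-positive equivalised income: EHII undefined")
  class(out) <- c("child_population", "data.frame")
  out
}

#' Write / read the person-level household table
#'
#' CSV interface with the canonical column layout (`disposable_income_month`
#' for the income column).
#'
#' @param pop Person-level population.
#' @param path File path.
#' @return `read_population()` returns a `silc_population` data frame.
#' @export
write_population <- function(pop, path) {
  out <- data.frame(
    household_id = pop$household_id, person_id = pop$person_id,
    age = pop$age, sex = pop$sex, is_mother = pop$is_mother,
    disposable_income_month = pop$disposable_income,
    survey_weight = pop$survey_weight, mother_age = pop$mother_age,
    mother_foreign = pop$mother_foreign
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("household_id", "person_id", "age", "sex", "is_mother",
            "disposable_income_month", "survey_weight", "mother_age",
            "mother_foreign")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  names(x)[names(x) == "disposable_income_month"] <- "disposable_income"
  class(x) <- c("silc_population", "data.frame")
  x
}
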