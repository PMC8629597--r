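#' Default covariate distributions for the synthetic birth cohort
#'
#' Emulates the marginal covariate structure of an internet-based Italian
#' birth cohort: log equivalised income 7.38 [0.26], maternal age 33.3
#' [4.4] years, 4.2\% foreign-born mothers, 49.3\% girls.
#'
#' @return Named list of distribution parameters.
#' @export
cohort_covariate_defaults <- function() {
  list(ehii_mean = 7.38, ehii_sd = 0.26,
       mother_age_mean = 33.3, mother_age_sd = 4.4,
       p_foreign = 0.042, p_female = 0.493)
}

#' Generate a synthetic birth cohort from known chain parameters
#'
#' Covariates are drawn from the configured marginal distributions; the
#' seven outcomes are then generated sequentially from the chain equations,
#' each as its linear predictor plus a Gaussian residual with the equation's
#' `residual_sd`. Downstream outcomes are always generated from the true
#' (unmasked) values of their predecessors; missingness only hides
#' observations, mimicking the declining follow-up of a dynamic cohort.
#'
#' @param n Cohort size (positive integer).
#' @param truths A complete `chain_model` supplying the generating
#'   parameters (default [table3_parameters()]).
#' @param covariate_params See [cohort_covariate_defaults()]; partial lists
#'   are merged over the defaults.
#' @param missingness Optional named vector of per-outcome missingness
#'   probabilities (independent masking), e.g. `c(bmi120 = 0.9)`.
#' @param seed Optional integer seed.
#' @return A `data.frame` with columns `ehii`, `sex`, `mother_age`,
#'   `mother_foreign`, and the outcomes `ga` (weeks), `bw`, `wt6`, `wt18`
#'   (hectograms), `bmi48`, `bmi84`, `bmi120` (kg/m^2).
#' @export
synthetic_cohort <- function(n, truths = table3_parameters(),
                             covariate_params = list(),
                             missingness = NULL, seed = NULL) {
  if (length(n) != 1 || is.na(n) || n < 1) stop("'n' must be positive")
  cp <- modifyList(cohort_covariate_defaults(), covariate_params)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  d <- data.frame(
    ehii           = rnorm(n, cp$ehii_mean, cp$ehii_sd),
    sex            = rbinom(n, 1, cp$p_female),
    mother_age     = rnorm(n, cp$mother_age_mean, cp$mother_age_sd),
    mother_foreign = rbinom(n, 1, cp$p_foreign)
  )
  for (out in chain_outcomes) {
    eq <- truths$equations[[out]]
    mu <- linear_predictor(eq, d, eq$coef)
    d[[out]] <- mu + rnorm(n, 0, eq$residual_sd)
  }
  if (!is.null(missingness)) {
    for (out in names(missingness)) {
      if (!out %in% chain_outcomes) stop("unknown outcome: ", out)
      d[[out]][runif(n) < missingness[[out]]] <- NA_real_
    }
  }
  d
}

# Linear predictor of one equation on a data frame holding the covariates
# and any required lagged outcomes; 'coefs' allows a sampled coefficient
# vector to replace the point estimates.
linear_predictor <- function(eq, data, coefs) {
  mu <- rep(coefs[["(Intercept)"]], nrow(data))
  for (term in eq$predictors) mu <- mu + coefs[[term]] * data[[term]]
  mu
}

#' Fit the seven concatenated regressions on cohort data
#'
#' Each equation is fit by ordinary least squares on the complete cases for
#' that equation (outcome, its lagged outcomes, and the shared covariates),
#' so equation-specific sample sizes decline naturally when later outcomes
#' are increasingly missing. The full estimated variance-covariance matrix
#' is retained per equation.
#'
#' @param cohort Data frame with columns `ehii`, `sex`, `mother_age`,
#'   `mother_foreign` and the seven outcomes (missing values allowed).
#' @param min_cases Minimum complete cases per equation (default 30).
#' @return A `chain_model` with `source = "fitted"`.
#' @export
fit_concatenated <- function(cohort, min_cases = 30) {
  eqs <- lapply(chain_outcomes, function(out) {
    preds <- c(chain_lags[[out]], chain_covariates)
    vars <- c(out, preds)
    miss <- setdiff(vars, names(cohort))
    if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
    cc <- complete.cases(cohort[vars])
    if (sum(cc) < min_cases)
      stop(sprintf("equation '%s': only %d complete cases (need >= %d)",
                   out, sum(cc), min_cases))
    fml <- as.formula(paste(out, "~", paste(preds, collapse = " + ")))
    fit <- lm(fml, data = cohort[cc, vars])
    if (any(is.na(coef(fit))))
      stop(sprintf("equation '%s' is rank deficient", out))
    sm <- summary(fit)
    se <- sqrt(diag(vcov(fit)))
    est <- coef(fit)
    ci <- cbind(lower = est - qnorm(0.975) * se,
                upper = est + qnorm(0.975) * se)
    fitted_equation(out, est, vcov(fit), residual_sd = sm$sigma,
                    n_obs = as.integer(sum(cc)), r2 = sm$r.squared, ci = ci)
  })
  chain_model(eqs, source = "fitted")
}

#' Write / read a cohort table as CSV
#'
#' Internally weights are in hectograms; on disk they may be stored in
#' grams (`weight_unit = "g"`, the default, matching how birth weights are
#' usually recorded) or hectograms.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @param weight_unit `"g"` or `"hg"` for the on-disk unit of `bw`, `wt6`,
#'   `wt18`.
#' @return `read_cohort()` returns a cohort data frame in internal units.
#' @export
write_cohort <- function(cohort, path, weight_unit = c("g", "hg")) {
  weight_unit <- match.arg(weight_unit)
  out <- cohort
  if (weight_unit == "g")
    for (v in c("bw", "wt6", "wt18"))
      if (v %in% names(out)) out[[v]] <- out[[v]] * 100
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, weight_unit = c("g", "hg")) {
  weight_unit <- match.arg(weight_unit)
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (weight_unit == "g")
    for (v in c("bw", "wt6", "wt18"))
      if (v %in% names(x)) x[[v]] <- x[[v]] / 100
  x
}
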