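# Chain structure: each outcome depends on the two preceding outcomes
# (the first on none, the second on one), plus EHII and the shared
# covariates. Weights are in hectograms throughout (see the methods
# vignette for the unit resolution); BMI in kg/m^2, GA in weeks.

chain_outcomes <- c("ga", "bw", "wt6", "wt18", "bmi48", "bmi84", "bmi120")

chain_lags <- list(
  ga     = character(0),
  bw     = "ga",
  wt6    = c("bw", "ga"),
  wt18   = c("wt6", "bw"),
  bmi48  = c("wt18", "wt6"),
  bmi84  = c("bmi48", "wt18"),
  bmi120 = c("bmi84", "bmi48")
)

chain_covariates <- c("ehii", "mother_age", "mother_foreign", "sex")

#' Construct one fitted chain equation
#'
#' @param outcome One of `ga`, `bw`, `wt6`, `wt18`, `bmi48`, `bmi84`,
#'   `bmi120`.
#' @param coef Named coefficient vector in the order `"(Intercept)"`,
#'   lagged outcomes, `ehii`, `mother_age`, `mother_foreign`, `sex`.
#' @param vcov Variance-covariance matrix over the coefficients (symmetric,
#'   positive semi-definite, same dimension and order as `coef`).
#' @param residual_sd Residual standard deviation in outcome units (> 0).
#' @param n_obs Number of observations the equation was estimated on.
#' @param r2 Coefficient of determination.
#' @param ci Optional 2-column matrix of 95\% CI bounds per coefficient.
#' @return An object of class `fitted_equation`.
#' @export
fitted_equation <- function(outcome, coef, vcov, residual_sd,
                            n_obs = NA_integer_, r2 = NA_real_, ci = NULL) {
  outcome <- match.arg(outcome, chain_outcomes)
  expected <- c("(Intercept)", chain_lags[[outcome]], chain_covariates)
  if (!identical(names(coef), expected))
    stop(sprintf("coefficients of '%s' must be named: %s", outcome,
                 paste(expected, collapse = ", ")))
  if (!is.matrix(vcov) || any(dim(vcov) != length(coef)))
    stop("'vcov' dimension must match the coefficient vector")
  if (residual_sd < 0) stop("'residual_sd' must be >= 0")
  structure(list(outcome = outcome, predictors = expected[-1], coef = coef,
                 vcov = vcov, residual_sd = residual_sd,
                 n_obs = n_obs, r2 = r2, ci = ci),
            class = "fitted_equation")
}

#' Assemble a chain model from its seven equations
#'
#' @param equations List of seven `fitted_equation` objects, one per
#'   outcome, in chain order.
#' @param source `"table3"` for the packaged published preset or
#'   `"fitted"` for a chain estimated from cohort data.
#' @return An object of class `chain_model`.
#' @export
chain_model <- function(equations, source = "fitted") {
  if (!identical(vapply(equations, `[[`, "", "outcome"), chain_outcomes))
    stop("'equations' must cover the seven outcomes in chain order")
  names(equations) <- chain_outcomes
  structure(list(equations = equations, source = source),
            class = "chain_model")
}

#' @export
print.chain_model <- function(x, ...) {
  cat(sprintf("<chain_model> 7 concatenated equations (source: %s)\n",
              x$source))
  for (eq in x$equations) {
    cat(sprintf("  %-6s ~ %-28s  delta(ehii) = %+.3f  sigma = %.3f%s\n",
                eq$outcome,
                paste(eq$predictors[!eq$predictors %in% chain_covariates],
                      collapse = " + "),
                eq$coef[["ehii"]], eq$residual_sd,
                if (is.na(eq$n_obs)) "" else sprintf("  n = %d", eq$n_obs)))
  }
  invisible(x)
}

# Published coefficient table: point estimate with 95% CI bounds per term,
# per-equation n, R^2, and the marginal outcome SD used to back out the
# residual scale. Terms are ordered intercept, lags, ehii, mother_age,
# mother_foreign, sex. Weight-equation units: hectograms.
.published_chain <- list(
  ga = list(n = 6387L, r2 = 0.01, marginal_sd = 1.8,
    est = c(38.83, 0.31, -0.05, 0.02, -0.05),
    lo  = c(37.39, 0.11, -0.06, -0.19, -0.13),
    hi  = c(40.27, 0.51, -0.04, 0.22, 0.04)),
  bw = list(n = 6202L, r2 = 0.37, marginal_sd = 4.99,
    est = c(-31.01, 1.70, -0.55, 0.03, 0.65, -1.39),
    lo  = c(-34.98, 1.63, -0.99, 0.01, 0.11, -1.58),
    hi  = c(-27.03, 1.76, -0.10, 0.06, 1.19, -1.19)),
  wt6 = list(n = 5173L, r2 = 0.28, marginal_sd = 9.42,
    est = c(73.19, 0.89, -0.46, -0.60, -0.05, 1.88, -4.46),
    lo  = c(64.52, 0.83, -0.62, -1.58, -0.11, 0.66, -4.90),
    hi  = c(81.86, 0.94, -0.29, 0.39, 0.00, 3.09, -4.02)),
  wt18 = list(n = 4141L, r2 = 0.46, marginal_sd = 12.85,
    est = c(32.69, 0.83, 0.23, 1.36, -0.02, -1.30, -1.47),
    lo  = c(22.92, 0.79, 0.16, 0.07, -0.09, -2.82, -2.07),
    hi  = c(42.47, 0.87, 0.30, 2.65, 0.05, 0.23, -0.86)),
  bmi48 = list(n = 2923L, r2 = 0.20, marginal_sd = 1.7,
    est = c(10.70, 0.05, 0.01, -0.31, 0.00, -0.20, 0.29),
    lo  = c(8.75, 0.05, 0.00, -0.57, -0.02, -0.54, 0.18),
    hi  = c(12.66, 0.06, 0.02, -0.05, 0.01, 0.14, 0.41)),
  bmi84 = list(n = 1621L, r2 = 0.26, marginal_sd = 2.1,
    est = c(8.73, 0.55, 0.02, -0.52, 0.00, -0.01, 0.16),
    lo  = c(5.55, 0.48, 0.01, -0.93, -0.02, -0.62, -0.01),
    hi  = c(11.92, 0.63, 0.03, -0.10, 0.03, 0.61, 0.34)),
  bmi120 = list(n = 658L, r2 = 0.49, marginal_sd = 2.6,
    est = c(7.62, 0.77, 0.27, -0.85, -0.01, 0.17, -0.12),
    lo  = c(2.03, 0.67, 0.15, -1.58, -0.05, -0.87, -0.40),
    hi  = c(13.22, 0.88, 0.39, -0.12, 0.03, 1.22, 0.17))
)

#' The published regression-chain parameter preset
#'
#' Returns the chain preloaded with the published coefficients of the seven
#' concatenated growth regressions: gestational age, birth weight, weight at
#' 6 and 18 months (hectograms), and BMI at 48, 84 and 120 months, each
#' regressed on its two preceding outcomes, log equivalised income (EHII),
#' maternal age at delivery, maternal country of birth (0 = Italy,
#' 1 = other) and child sex (0 = male, 1 = female).
#'
#' Standard errors are recovered from the printed 95\% CIs as
#' `(upper - lower) / (2 x 1.96)`. The residual scale of each equation is
#' the marginal outcome SD times `sqrt(1 - R^2)`.
#'
#' Only the marginal SEs are published, not the coefficient covariances,
#' yet the joint distribution matters for Monte Carlo sampling: in an OLS
#' fit the intercept is strongly negatively correlated with the slopes, so
#' drawing coefficients independently (`vcov = "diagonal"`) inflates the
#' variance of the predicted mean by orders of magnitude and with it every
#' simulated prevalence. The default `vcov = "design"` therefore rebuilds
#' each equation's coefficient *correlation* matrix from the OLS
#' information matrix of a fixed reference cohort design (the packaged
#' synthetic-cohort covariate distributions) and scales it by the printed
#' SEs, preserving every published marginal SE while keeping the predicted
#' mean's sampling variance at its natural `sigma^2 / n` scale.
#'
#' @param vcov `"design"` (default) or `"diagonal"`, see Details.
#' @return A `chain_model` with `source = "table3"`.
#' @examples
#' chain <- table3_parameters()
#' chain$equations$bmi120$coef[["ehii"]]  # -0.85
#' @export
table3_parameters <- function(vcov = c("design", "diagonal")) {
  vcov <- match.arg(vcov)
  eqs <- lapply(chain_outcomes, function(out) {
    p <- .published_chain[[out]]
    nm <- c("(Intercept)", chain_lags[[out]], chain_covariates)
    est <- setNames(p$est, nm)
    se <- (p$hi - p$lo) / (2 * qnorm(0.975))
    ci <- cbind(lower = setNames(p$lo, nm), upper = setNames(p$hi, nm))
    V0 <- diag(se^2, length(est))
    dimnames(V0) <- list(nm, nm)
    fitted_equation(out, est, V0,
                    residual_sd = p$marginal_sd * sqrt(1 - p$r2),
                    n_obs = p$n, r2 = p$r2, ci = ci)
  })
  chain <- chain_model(eqs, source = "table3")
  if (vcov == "design") {
    corr <- design_correlations(chain)
    for (out in chain_outcomes) {
      se <- sqrt(diag(chain$equations[[out]]$vcov))
      V <- diag(se) %*% corr[[out]] %*% diag(se)
      dimnames(V) <- list(names(se), names(se))
      chain$equations[[out]]$vcov <- V
    }
  }
  chain
}

# Coefficient correlation matrices implied by the OLS information matrix
# of a reference synthetic-cohort design (fixed internal seed; the global
# RNG state is preserved). Correlations are scale-free, so the reference
# cohort size only controls their estimation noise. Cached per session.
.chain_cache <- new.env(parent = emptyenv())

design_correlations <- function(chain, n_ref = 20000L) {
  key <- "design_correlations"
  if (!is.null(.chain_cache[[key]])) return(.chain_cache[[key]])
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  ref <- synthetic_cohort(n_ref, truths = chain, seed = 193021L)
  out <- lapply(chain_outcomes, function(o) {
    eq <- chain$equations[[o]]
    X <- cbind(1, as.matrix(ref[eq$predictors]))
    stats::cov2cor(solve(crossprod(X)))
  })
  names(out) <- chain_outcomes
  .chain_cache[[key]] <- out
  out
}

#' Total income effect on a chain outcome
#'
#' The total derivative of an outcome's conditional mean with respect to
#' EHII, accumulated through every path of the chain: the outcome's own
#' income coefficient plus the lag coefficients times the upstream
#' gradients.
#'
#' @param chain A `chain_model`.
#' @param outcome Outcome name.
#' @return Gradient in outcome units per unit of log equivalised income.
#' @examples
#' income_effect_gradient(table3_parameters(), "ga")  # 0.31
#' @export
income_effect_gradient <- function(chain, outcome) {
  outcome <- match.arg(outcome, chain_outcomes)
  g <- setNames(numeric(length(chain_outcomes)), chain_outcomes)
  for (out in chain_outcomes) {
    eq <- chain$equations[[out]]
    g[out] <- eq$coef[["ehii"]] +
      sum(vapply(chain_lags[[out]], function(l) eq$coef[[l]] * g[[l]], 0))
    if (out == outcome) break
  }
  unname(g[outcome])
}

#' Serialize / deserialize a chain model as JSON
#'
#' Full double precision is preserved, so a write/read round trip is
#' bit-exact.
#'
#' @param chain A `chain_model`.
#' @param path File path of the JSON parameter file.
#' @return `read_chain()` returns a `chain_model`.
#' @export
write_chain <- function(chain, path) {
  payload <- list(
    source = chain$source,
    equations = lapply(chain$equations, function(eq) {
      list(outcome = eq$outcome, terms = names(eq$coef),
           coef = unname(eq$coef), vcov = unname(eq$vcov),
           residual_sd = eq$residual_sd, n_obs = eq$n_obs, r2 = eq$r2,
           ci = if (is.null(eq$ci)) NULL else
             list(lower = unname(eq$ci[, "lower"]),
                  upper = unname(eq$ci[, "upper"])))
    })
  )
  # I(17) significant digits guarantees an exact double round trip
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  eqs <- lapply(chain_outcomes, function(out) {
    e <- x$equations[[out]]
    coef <- setNames(as.numeric(e$coef), e$terms)
    ci <- if (!is.null(e$ci) && length(e$ci))
      cbind(lower = setNames(as.numeric(e$ci$lower), e$terms),
            upper = setNames(as.numeric(e$ci$upper), e$terms))
    fitted_equation(out, coef, as.matrix(e$vcov),
                    residual_sd = e$residual_sd,
                    n_obs = if (is.null(e$n_obs)) NA_integer_ else
                      as.integer(e$n_obs),
                    r2 = if (is.null(e$r2)) NA_real_ else e$r2,
                    ci = ci)
  })
  chain_model(eqs, source = x$source)
}
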