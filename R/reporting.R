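#' Prevalence ratio of a scenario versus baseline
#'
#' With common random numbers, the per-run prevalence ratio
#' `PR_r = prev_scenario_r / prev_baseline_r` is exactly paired. The point
#' estimate is the mean of the per-run ratios and the interval its
#' 2.5th/97.5th percentiles.
#'
#' @param experiment A `scenario_experiment` from [run_experiment()].
#' @param scenario Scenario name (numerator).
#' @param baseline Baseline scenario name (denominator, default `"BS"`).
#' @param age_months One of 48, 84, 120.
#' @param category `"overweight"` or `"obesity"`.
#' @return List with `point`, `lower`, `upper` and the per-run ratios
#'   `runs`.
#' @export
prevalence_ratio <- function(experiment, scenario, baseline = "BS",
                             age_months = 120,
                             category = c("overweight", "obesity")) {
  category <- match.arg(category)
  a <- as.character(age_months)
  num <- experiment$prevalence[, scenario, a, category]
  den <- experiment$prevalence[, baseline, a, category]
  if (any(den == 0)) stop("zero baseline prevalence in at least one run")
  pr <- num / den
  qs <- unname(quantile(pr, c(0.025, 0.975)))
  list(point = mean(pr), lower = qs[1], upper = qs[2], runs = pr)
}

#' Scenario comparison table
#'
#' One row per (scenario, age, category): mean prevalences, the prevalence
#' ratio with its 95\% percentile interval, the percentage-point prevalence
#' reduction implied by the PR (`100 x prev_baseline x (1 - PR)`), and,
#' when annual costs are supplied, the cost of one percentage point of
#' prevalence reduction. Cells whose baseline prevalence is zero in some
#' run (possible for rare categories in small pilot populations) are
#' reported as `NA`.
#'
#' @param experiment A `scenario_experiment`.
#' @param baseline Baseline scenario name (default `"BS"`).
#' @param costs Optional named vector of annual scenario costs (euros/year)
#'   as from [scenario_cost()].
#' @return Data frame of class `comparison_table`.
#' @export
comparison_table <- function(experiment, baseline = "BS", costs = NULL) {
  scen <- setdiff(experiment$scenarios, baseline)
  ages <- as.integer(dimnames(experiment$prevalence)[[3]])
  cats <- dimnames(experiment$prevalence)[[4]]
  rows <- list()
  for (s in scen) for (a in ages) for (cat in cats) {
    pr <- tryCatch(prevalence_ratio(experiment, s, baseline, a, cat),
                   error = function(e) list(point = NA_real_,
                                            lower = NA_real_,
                                            upper = NA_real_))
    pb <- mean(experiment$prevalence[, baseline, as.character(a), cat])
    ps <- mean(experiment$prevalence[, s, as.character(a), cat])
    red <- 100 * pb * (1 - pr$point)
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = s, age_months = a, category = cat,
      prev_baseline = pb, prev_scenario = ps,
      pr = pr$point, pr_lower = pr$lower, pr_upper = pr$upper,
      reduction_pp = red,
      marginal_cost = if (is.null(costs)) NA_real_
                      else marginal_cost(costs[[s]], red),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Cost of one percentage point of prevalence reduction
#'
#' Annual scenario cost divided by the percentage-point prevalence
#' reduction it produces. A non-positive reduction makes the quantity
#' non-computable and yields `NA` (not infinity); CSV output renders it as
#' the sentinel `"NC"`.
#'
#' @param annual_cost Annual cost in euros/year (vectorised).
#' @param reduction_pp Prevalence reduction in percentage points.
#' @return Euros per percentage point, or `NA` where `reduction_pp <= 0`.
#' @export
marginal_cost <- function(annual_cost, reduction_pp) {
  ifelse(reduction_pp > 0, annual_cost / reduction_pp, NA_real_)
}

#' Weighted kernel density summary
#'
#' Gaussian-kernel density with Silverman's bandwidth, optionally weighted;
#' used for income and BMI distribution figures. The estimate integrates
#' to 1 on a sufficiently wide grid.
#'
#' @param values Numeric sample (at least 100 values).
#' @param weights Optional positive weights (normalised internally).
#' @param n_grid Number of grid points (default 512).
#' @param from,to Optional grid range (defaults to the range extended by
#'   three bandwidths, as in [stats::density()]).
#' @return Data frame with columns `x` and `density`.
#' @export
density_summary <- function(values, weights = NULL, n_grid = 512,
                            from = NULL, to = NULL) {
  if (length(values) < 100) stop("need at least 100 values")
  if (sd(values) == 0) stop("degenerate (zero-variance) sample")
  if (!is.null(weights)) weights <- weights / sum(weights)
  # Silverman bandwidth from the sample itself (weights only reweight mass)
  args <- list(x = values, bw = stats::bw.nrd0(values), kernel = "gaussian",
               n = n_grid, weights = weights)
  if (!is.null(from)) args$from <- from
  if (!is.null(to)) args$to <- to
  d <- do.call(density, args)
  data.frame(x = d$x, density = d$y)
}

#' Write a reproducible report bundle
#'
#' Writes the comparison table CSV (with `"NC"` for non-computable
#' marginal costs), the per-run prevalence CSV in long format, and a
#' run-metadata JSON (seed, number of runs, package and R versions, and the
#' configuration if given). Re-running with the same seed and inputs
#' reproduces the CSVs bit-exactly.
#'
#' @param experiment A `scenario_experiment`.
#' @param comparison A `comparison_table`.
#' @param out_dir Output directory (created if missing).
#' @param config Optional configuration list stored in the metadata.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(experiment, comparison, out_dir, config = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  comp_path <- file.path(out_dir, "comparison.csv")
  comp_out <- as.data.frame(comparison)
  comp_out$marginal_cost <- ifelse(is.na(comp_out$marginal_cost), "NC",
                                   format(comp_out$marginal_cost,
                                          digits = 15, scientific = TRUE,
                                          trim = TRUE))
  write.csv(comp_out, comp_path, row.names = FALSE)

  prev <- experiment$prevalence
  dn <- dimnames(prev)
  long <- expand.grid(run = seq_len(dim(prev)[1]), scenario = dn[[2]],
                      age_months = as.integer(dn[[3]]), category = dn[[4]],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$prevalence <- as.vector(prev)
  run_path <- file.path(out_dir, "per_run_prevalence.csv")
  write.csv(long, run_path, row.names = FALSE)

  meta <- list(master_seed = experiment$master_seed,
               n_runs = experiment$n_runs,
               n_children = experiment$n_children,
               scenarios = experiment$scenarios,
               overweight_includes_obese =
                 experiment$overweight_includes_obese,
               package_version = as.character(packageVersion("bmisim")),
               r_version = paste(R.version$major, R.version$minor, sep = "."),
               config = config)
  meta_path <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(comparison = comp_path, per_run = run_path,
              metadata = meta_path))
}
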