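#' Default pipeline configuration
#'
#' A nested list mirroring the YAML configuration accepted by
#' [read_config()] and the command-line interface, with blocks
#' `population`, `scenarios`, `chain`, `simulation`, `calibration` and
#' `output`.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    population = c(list(n_households = 20000, target_children = 30910),
                   population_defaults()),
    scenarios = "builtin",
    chain = list(source = "table3", file = NULL),
    simulation = list(n_runs = 1000, seed = 1L,
                      overweight_includes_obese = TRUE),
    calibration = c(list(enabled = TRUE), calibration_targets()),
    output = list(dir = "results", national_persons = 60.6e6)
  )
}

#' Read a YAML configuration file
#'
#' Values present in the file override the defaults; everything else keeps
#' its default. Custom scenarios may be given as a `scenarios:` list of
#' blocks with the [policy_scenario()] fields.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  modifyList(cfg, user)
}

#' Build scenario objects from a configuration
#'
#' @param cfg Configuration list from [read_config()].
#' @return Named list of `policy_scenario` objects.
#' @export
scenarios_from_config <- function(cfg) {
  sc <- cfg$scenarios
  if (identical(sc, "builtin")) return(builtin_scenarios())
  out <- lapply(sc, function(b) do.call(policy_scenario, b))
  names(out) <- vapply(out, `[[`, "", "name")
  if (!"BS" %in% names(out)) out <- c(builtin_scenarios()["BS"], out)
  out
}
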