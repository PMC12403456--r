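## One-call reproduction of a full policy table: benchmark, alternative,
## and every sensitivity modifier for a market setting.

.SUITE_POLICIES <- list(
  urban = list(benchmark = "urban_benchmark",
               alternative = "urban_price_support"),
  rural = list(benchmark = "rural_benchmark",
               alternative = "rural_full_price_support")
)

#' Run the full policy/sensitivity suite for one market setting
#'
#' Runs the setting's benchmark reallocation, its price-support
#' alternative, and the benchmark under every sensitivity modifier valid
#' in the setting, all from the same master seed, then assembles the
#' [results_table()] with the benchmark as reference.
#'
#' @param setting `"urban"` or `"rural"`.
#' @param seed master seed shared by all experiments (so the benchmark
#'   and alternative are bit-identical through the burn-in).
#' @param n_iterations,n_women scale of each experiment.
#' @param segments population segments to analyze; defaults to overall and
#'   low-income, use the four subgroup labels for the subgroup table.
#' @param ... further arguments passed to [experiment_spec()] (parameter
#'   lists, horizon, ...).
#' @return list of class `fp_suite` with `specs`, `fits` (per experiment,
#'   per segment), and `table` (an `fp_results_table`).
#' @export
run_suite <- function(setting = c("urban", "rural"), seed = 1,
                      n_iterations = 100, n_women = 100,
                      segments = c("overall", "low_income"), ...) {
  setting <- match.arg(setting)
  pol <- .SUITE_POLICIES[[setting]]
  specs <- list()
  specs[["benchmark"]] <- experiment_spec(
    setting, pol$benchmark, seed = seed, n_iterations = n_iterations,
    n_women = n_women, ...)
  specs[["alternative"]] <- experiment_spec(
    setting, pol$alternative, seed = seed, n_iterations = n_iterations,
    n_women = n_women, ...)
  for (m in modifier_names(setting))
    specs[[m]] <- experiment_spec(
      setting, pol$benchmark, modifier = m, seed = seed,
      n_iterations = n_iterations, n_women = n_women, ...)
  fits <- lapply(specs, function(sp)
    analyze_experiment(run_experiment(sp), segments))
  structure(list(specs = specs, fits = fits,
                 table = results_table(fits, benchmark = "benchmark")),
            class = "fp_suite")
}

#' @export
print.fp_suite <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' A small deterministic test population
#'
#' Eight women, two per income x sensitivity subgroup, on fixed grid
#' locations with class-mean earnings: one of each pair near the public
#' (lower-left) corner and one near the private (upper-right) corner, so
#' rural travel costs differ within every subgroup.
#'
#' @param params a [population_params()] (class means and grid size are
#'   honored; the income spread is ignored: earnings are the class means).
#' @return a [generate_population()]-shaped data frame with 8 rows.
#' @export
fixture_population <- function(params = population_params()) {
  cells <- .subgroup_cells()
  g <- params$grid_size
  near <- g / 4
  far <- 3 * g / 4
  income_class <- rep(cells$income_class, each = 2)
  sensitivity <- rep(cells$quality_sensitivity, each = 2)
  annual <- ifelse(income_class == "low", params$earnings_low,
                   params$earnings_high)
  data.frame(
    id = 1:8,
    income_class = factor(income_class, levels = c("low", "high")),
    quality_sensitivity = factor(sensitivity, levels = c("low", "high")),
    subgroup = factor(rep(cells$subgroup, each = 2),
                      levels = .SUBGROUP_LEVELS),
    sigma = ifelse(sensitivity == "low", params$sigma_low,
                   params$sigma_high),
    annual_earnings = annual,
    weekly_cash = annual / 52,
    x = rep(c(near, far), 4), y = rep(c(near, far), 4),
    protection_months = 0L,
    belief_public = NA_real_,
    belief_private = NA_real_
  )
}
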