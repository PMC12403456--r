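## Run configuration: a YAML file fully resolvable to an experiment spec,
## with validation that names the offending key, plus panel/table/manifest
## serialization.

.CONFIG_KEYS <- list(
  top = c("setting", "policy", "pre_policy", "modifier", "n_iterations",
          "n_women", "seed", "horizon", "switch_month", "tie_break",
          "market", "population", "vendors", "behavior", "conversion",
          "output"),
  market = c("travel_cost_per_mile"),
  population = c("earnings_low", "earnings_high", "income_spread",
                 "sigma_low", "sigma_high", "grid_size"),
  vendors = c("public_quality", "private_quality", "private_price",
              "public_wait", "private_wait"),
  behavior = c("alpha", "beta_uip", "acceptance", "p0", "e_base", "omega",
               "n_max", "prior_quality"),
  conversion = c("budget", "kappa_quality", "kappa_adv", "kappa_price"),
  policy = c("target_sector", "share_perceived_quality",
             "share_true_quality", "share_price_support", "budget"),
  output = c("panel", "manifest", "table")
)

.check_keys <- function(block, valid, where) {
  if (is.null(block)) return(invisible())
  .assert(is.list(block), "config section '%s' must be a mapping", where)
  bad <- setdiff(names(block), valid)
  .assert(length(bad) == 0L, "unknown config key%s in '%s': %s",
          if (length(bad) > 1) "s" else "", where,
          paste(bad, collapse = ", "))
  invisible()
}

#' Default run configuration
#'
#' The fully explicit configuration underlying the default
#' [experiment_spec()]: every tunable parameter with its frozen default.
#' [load_config()] merges a user file over this.
#'
#' @return nested list mirroring the YAML config layout.
#' @export
default_config <- function() {
  pp <- population_params(); vp <- vendor_params()
  bp <- behavior_params(); cp <- conversion_params()
  ms <- market_setting()
  list(setting = "urban", policy = "urban_benchmark",
       pre_policy = "public_baseline", modifier = "none",
       n_iterations = 100L, n_women = 100L, seed = 1L,
       horizon = 120L, switch_month = 61L, tie_break = "random",
       market = list(travel_cost_per_mile = ms$travel_cost_per_mile),
       population = unclass(pp), vendors = unclass(vp),
       behavior = unclass(bp),
       conversion = unclass(cp)[!vapply(unclass(cp), is.null, logical(1))],
       output = list())
}

## Merge user values over defaults (one level of nesting).
.merge_config <- function(user, defaults) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !k %in% c("policy", "pre_policy", "output")) {
      for (k2 in names(user[[k]])) defaults[[k]][[k2]] <- user[[k]][[k2]]
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Turn a configuration list into an experiment spec
#'
#' Validates key names and ranges (errors name the offending key), fills
#' in every default, and builds the [experiment_spec()]. `policy` and
#' `pre_policy` may be [named_policy()] names or explicit allocation
#' mappings.
#'
#' @param config nested list as produced by reading a config file.
#' @return an `fp_experiment_spec` with the resolved config attached as
#'   attribute `"config"`.
#' @export
as_experiment_spec <- function(config) {
  .check_keys(config, .CONFIG_KEYS$top, "top level")
  for (sec in c("market", "population", "vendors", "behavior",
                "conversion", "output"))
    .check_keys(config[[sec]], .CONFIG_KEYS[[sec]], sec)
  cfg <- .merge_config(config, default_config())

  pp <- do.call(population_params, cfg$population)
  vp <- do.call(vendor_params, cfg$vendors)
  bp <- do.call(behavior_params, cfg$behavior)
  cp <- do.call(conversion_params, cfg$conversion)
  setting <- market_setting(cfg$setting, grid_size = pp$grid_size,
                            travel_cost_per_mile =
                              cfg$market$travel_cost_per_mile)

  as_policy <- function(x, field) {
    if (is.character(x)) return(x)
    .check_keys(x, .CONFIG_KEYS$policy, field)
    if (is.null(x$budget)) x$budget <- cp$budget
    do.call(policy_allocation, x)
  }
  spec <- experiment_spec(
    setting = setting,
    post_policy = as_policy(cfg$policy, "policy"),
    pre_policy = as_policy(cfg$pre_policy, "pre_policy"),
    modifier = cfg$modifier,
    n_iterations = cfg$n_iterations, n_women = cfg$n_women,
    seed = cfg$seed, horizon = cfg$horizon,
    switch_month = cfg$switch_month,
    population = pp, vendors = vp, behavior = bp, conversion = cp,
    tie_break = cfg$tie_break)
  attr(spec, "config") <- cfg
  spec
}

#' Load and validate a YAML run configuration
#'
#' @param path path to a YAML file; any subset of the keys in
#'   [default_config()] may be given, missing ones take their defaults.
#' @return an `fp_experiment_spec` (see [as_experiment_spec()]).
#' @export
load_config <- function(path) {
  .assert(file.exists(path), "config file '%s' does not exist", path)
  config <- yaml::read_yaml(path)
  .assert(is.list(config), "config file '%s' is not a YAML mapping", path)
  as_experiment_spec(config)
}

#' Write the run manifest
#'
#' Serializes every resolved parameter of a spec (plus the per-iteration
#' seed rule and package version) as YAML, sufficient to reproduce the run
#' exactly.
#'
#' @param spec an `fp_experiment_spec`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(spec, path) {
  .assert(inherits(spec, "fp_experiment_spec"),
          "'spec' must come from experiment_spec()")
  rp <- .resolve_spec(spec)
  kp <- spec$conversion$kappa_price
  if (is.null(kp))
    kp <- calibrate_price_support(spec$vendors$private_price,
                                  spec$conversion$budget)
  manifest <- list(
    package = "fpmarket",
    version = as.character(utils::packageVersion("fpmarket")),
    setting = unclass(spec$setting),
    n_iterations = spec$n_iterations, n_women = spec$n_women,
    seed = spec$seed, iteration_seed_rule = "seed + iteration",
    horizon = spec$horizon, switch_month = spec$switch_month,
    modifier = spec$modifier, tie_break = spec$tie_break,
    pre_policy = unclass(spec$pre_policy),
    post_policy = unclass(spec$post_policy),
    population = unclass(spec$population),
    vendors = unclass(spec$vendors),
    behavior = unclass(spec$behavior),
    behavior_modified = unclass(rp$behavior),
    vendors_modified = unclass(rp$vendors),
    travel_cost_modified = rp$setting$travel_cost_per_mile,
    conversion = c(unclass(spec$conversion)[
      !vapply(unclass(spec$conversion), is.null, logical(1))],
      list(kappa_price_resolved = kp)))
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Write / read a simulation panel as delimited text
#'
#' Comma-separated with a header; columns `iteration`, `month`,
#' `woman_id`, `income_class`, `quality_sensitivity`, `subgroup`,
#' `protected`, `vendor`.
#'
#' @param panel an `fp_panel`.
#' @param path output (input) file.
#' @return `path` invisibly for the writer; an `fp_panel` (without the
#'   spec attribute) for the reader.
#' @export
write_panel <- function(panel, path) {
  .assert(is.data.frame(panel), "'panel' must be a data frame")
  utils::write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  .assert(file.exists(path), "panel file '%s' does not exist", path)
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  panel$income_class <- factor(panel$income_class, levels = c("low", "high"))
  panel$quality_sensitivity <- factor(panel$quality_sensitivity,
                                      levels = c("low", "high"))
  panel$subgroup <- factor(panel$subgroup, levels = .SUBGROUP_LEVELS)
  panel$protected <- as.logical(panel$protected)
  panel$vendor <- factor(panel$vendor,
                         levels = c("none", "public", "private"))
  class(panel) <- c("fp_panel", "data.frame")
  panel
}

#' Write a results table as delimited text
#'
#' The long numeric form of an [results_table()] (one row per experiment
#' x segment), re-readable with [read_results_table()].
#'
#' @param x an `fp_results_table`.
#' @param path output (input) file.
#' @return `path` invisibly for the writer; the table for the reader.
#' @export
write_results_table <- function(x, path) {
  .assert(inherits(x, "fp_results_table"),
          "'x' must come from results_table()")
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  .assert(file.exists(path), "results file '%s' does not exist", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$stars[is.na(out$stars)] <- ""
  class(out) <- c("fp_results_table", "data.frame")
  out
}
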