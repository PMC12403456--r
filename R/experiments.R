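## Policy allocations, sensitivity modifiers, and the burn-in/switch
## experiment runner.

#' Policy allocation of the fixed budget
#'
#' Splits the monthly policy budget among truthful quality advertising
#' ("perceived quality"), true quality improvement, and private-sector
#' price support, all flowing to one target sector.
#'
#' @param target_sector `"public"` or `"private"`.
#' @param share_perceived_quality,share_true_quality,share_price_support
#'   non-negative budget shares summing to 1. Price support must be 0 when
#'   the target is the public sector (its price is already zero).
#' @param budget total monthly budget B (money units).
#' @return a list of class `fp_policy`.
#' @export
policy_allocation <- function(target_sector = c("public", "private"),
                              share_perceived_quality = 0,
                              share_true_quality = 1,
                              share_price_support = 0,
                              budget = 100) {
  target_sector <- match.arg(target_sector)
  .assert_number(share_perceived_quality, "share_perceived_quality", 0, 1)
  .assert_number(share_true_quality, "share_true_quality", 0, 1)
  .assert_number(share_price_support, "share_price_support", 0, 1)
  .assert_number(budget, "budget", lower = 1e-12)
  total <- share_perceived_quality + share_true_quality + share_price_support
  .assert(abs(total - 1) < 1e-8,
          "allocation shares must sum to 1 (got %s)", format(total))
  if (target_sector == "public")
    .assert(share_price_support == 0,
            "price support cannot target the public sector")
  structure(list(target_sector = target_sector,
                 share_perceived_quality = share_perceived_quality,
                 share_true_quality = share_true_quality,
                 share_price_support = share_price_support,
                 budget = budget),
            class = "fp_policy")
}

.NAMED_POLICIES <- list(
  public_baseline = list(target = "public", shares = c(0, 1, 0),
                         setting = NA_character_),
  urban_benchmark = list(target = "private", shares = c(0.20, 0.80, 0),
                         setting = "urban"),
  urban_price_support = list(target = "private", shares = c(0.20, 0.60, 0.20),
                             setting = "urban"),
  rural_benchmark = list(target = "private", shares = c(0.20, 0.60, 0.20),
                         setting = "rural"),
  rural_full_price_support = list(target = "private",
                                  shares = c(0.20, 0.40, 0.40),
                                  setting = "rural")
)

#' The named policy allocations of the study design
#'
#' `public_baseline` is the pre-switch regime: the whole budget sustains
#' public-sector quality. The benchmark reallocation sends 20% to
#' advertising and 80% to true quality at the private vendor
#' (`urban_benchmark`); the urban alternative and the rural benchmark
#' convert 20 points of the quality share into price support
#' (20/60/20); the rural alternative converts a further 20 into full price
#' support (20/40/40), which drives the private price to zero under the
#' [calibrate_price_support()] calibration.
#'
#' @param name one of `public_baseline`, `urban_benchmark`,
#'   `urban_price_support`, `rural_benchmark`, `rural_full_price_support`.
#' @param setting optional `"urban"`/`"rural"` (or a [market_setting()]);
#'   if given, a policy tied to the other geometry is rejected.
#' @param budget total monthly budget B.
#' @return an [policy_allocation()].
#' @export
named_policy <- function(name, setting = NULL, budget = 100) {
  .assert(is.character(name) && length(name) == 1L,
          "'name' must be a single string")
  if (!name %in% names(.NAMED_POLICIES))
    stop(sprintf("unknown policy '%s'; valid names: %s", name,
                 paste(names(.NAMED_POLICIES), collapse = ", ")),
         call. = FALSE)
  p <- .NAMED_POLICIES[[name]]
  if (!is.null(setting)) {
    mode <- if (inherits(setting, "fp_market_setting")) setting$mode else setting
    .assert(is.na(p$setting) || identical(p$setting, mode),
            "policy '%s' is defined for the %s setting, not '%s'",
            name, p$setting, mode)
  }
  policy_allocation(p$target, p$shares[1], p$shares[2], p$shares[3],
                    budget = budget)
}

.MODIFIERS <- list(
  none = list(field = "none", factor = 1, mode = NA_character_),
  longer_wait = list(field = "wait", factor = 1.25, mode = "urban"),
  shorter_wait = list(field = "wait", factor = 0.75, mode = "urban"),
  longer_travel = list(field = "travel", factor = 1.25, mode = "rural"),
  shorter_travel = list(field = "travel", factor = 0.75, mode = "rural"),
  fp_resistant = list(field = "acceptance", factor = 0.75, mode = NA_character_),
  reduced_effectiveness = list(field = "e_base", factor = 0.75, mode = NA_character_),
  enhanced_effectiveness = list(field = "e_base", factor = 1.25, mode = NA_character_),
  consumption_driven = list(field = "alpha", factor = 1.25, mode = NA_character_),
  consumption_indifferent = list(field = "alpha", factor = 0.75, mode = NA_character_),
  uip_driven = list(field = "beta_uip", factor = 1.25, mode = NA_character_),
  uip_indifferent = list(field = "beta_uip", factor = 0.75, mode = NA_character_)
)

#' Names of the sensitivity modifiers valid in a market setting
#'
#' @param mode `"urban"`, `"rural"`, or `NULL` for all modifiers.
#' @return character vector of modifier names (excluding `"none"`).
#' @export
modifier_names <- function(mode = NULL) {
  nm <- setdiff(names(.MODIFIERS), "none")
  if (is.null(mode)) return(nm)
  keep <- vapply(.MODIFIERS[nm], function(m)
    is.na(m$mode) || identical(m$mode, mode), logical(1))
  nm[keep]
}

#' Apply a sensitivity modifier to a parameter set
#'
#' Each modifier scales exactly one structural parameter by +/- 25% and is
#' active for the entire simulation horizon: wait times (urban only),
#' travel cost (rural only), FP acceptance (`fp_resistant`, x0.75),
#' base effectiveness (`reduced_`/`enhanced_effectiveness`; `e(q)` is
#' still clipped at 1), the consumption weight `alpha`
#' (`consumption_driven`/`_indifferent`), or the unintended-pregnancy
#' weight `beta_uip` (`uip_driven`/`_indifferent`). `"none"` is the
#' identity.
#'
#' @param params list with elements `behavior` ([behavior_params()]),
#'   `setting` ([market_setting()]) and `vendors` ([vendor_params()]).
#' @param modifier a modifier name (see [modifier_names()]).
#' @return `params` with exactly one field rescaled.
#' @export
apply_modifier <- function(params, modifier = "none") {
  .assert(is.list(params) &&
            all(c("behavior", "setting", "vendors") %in% names(params)),
          "'params' needs elements behavior, setting and vendors")
  .assert(is.character(modifier) && length(modifier) == 1L,
          "'modifier' must be a single string")
  if (!modifier %in% names(.MODIFIERS))
    stop(sprintf("unknown modifier '%s'; valid names: none, %s", modifier,
                 paste(modifier_names(), collapse = ", ")), call. = FALSE)
  m <- .MODIFIERS[[modifier]]
  if (!is.na(m$mode))
    .assert(identical(params$setting$mode, m$mode),
            "modifier '%s' is only valid in the %s setting", modifier, m$mode)
  switch(m$field,
         none = NULL,
         wait = {
           params$vendors$public_wait <- params$vendors$public_wait * m$factor
           params$vendors$private_wait <- params$vendors$private_wait * m$factor
         },
         travel = {
           params$setting$travel_cost_per_mile <-
             params$setting$travel_cost_per_mile * m$factor
         },
         acceptance = {
           params$behavior$acceptance <- params$behavior$acceptance * m$factor
         },
         e_base = {
           params$behavior$e_base <- params$behavior$e_base * m$factor
         },
         alpha = {
           params$behavior$alpha <- params$behavior$alpha * m$factor
         },
         beta_uip = {
           params$behavior$beta_uip <- params$behavior$beta_uip * m$factor
         })
  params
}

#' Specify a burn-in/policy-switch experiment
#'
#' Months 1 to `switch_month - 1` run under the pre-switch allocation
#' (default: the whole budget sustains public quality) so the market
#' reaches equilibrium; from `switch_month` on the budget flows to the
#' post-switch allocation. A sensitivity modifier, if any, is active from
#' month 1. Each iteration draws a fresh population from its own seed
#' (`seed + iteration`).
#'
#' @param setting `"urban"`, `"rural"`, or a [market_setting()].
#' @param post_policy the post-switch [policy_allocation()], or a
#'   [named_policy()] name.
#' @param pre_policy the pre-switch allocation (default
#'   `public_baseline`).
#' @param modifier a sensitivity modifier name (default `"none"`).
#' @param n_iterations,n_women Monte-Carlo iterations and women per
#'   iteration.
#' @param seed master seed; iteration `i` is seeded with `seed + i`.
#' @param horizon months simulated (default 120).
#' @param switch_month first month under the post-switch policy
#'   (default 61).
#' @param population,vendors,behavior,conversion parameter lists; see
#'   [population_params()], [vendor_params()], [behavior_params()],
#'   [conversion_params()].
#' @param tie_break how the engine resolves exact between-vendor ties
#'   (default `"random"`, a seeded fair coin; see [choose_plan()]).
#' @return a list of class `fp_experiment_spec`.
#' @export
experiment_spec <- function(setting = "urban",
                            post_policy = "urban_benchmark",
                            pre_policy = "public_baseline",
                            modifier = "none",
                            n_iterations = 100, n_women = 100, seed = 1,
                            horizon = 120, switch_month = 61,
                            population = population_params(),
                            vendors = vendor_params(),
                            behavior = behavior_params(),
                            conversion = conversion_params(),
                            tie_break = c("random", "deterministic")) {
  if (is.character(setting))
    setting <- market_setting(setting, grid_size = population$grid_size)
  .assert(inherits(setting, "fp_market_setting"),
          "'setting' must be 'urban', 'rural', or a market_setting()")
  if (is.character(post_policy))
    post_policy <- named_policy(post_policy, setting,
                                budget = conversion$budget)
  if (is.character(pre_policy))
    pre_policy <- named_policy(pre_policy, budget = conversion$budget)
  .assert(inherits(post_policy, "fp_policy") && inherits(pre_policy, "fp_policy"),
          "policies must be fp_policy allocations or named_policy() names")
  .assert(.is_number(n_iterations) && n_iterations >= 1,
          "'n_iterations' must be a positive integer")
  .assert(.is_number(n_women) && n_women >= 1,
          "'n_women' must be a positive integer")
  .assert(.is_number(seed) && seed == as.integer(seed),
          "'seed' must be an integer")
  .assert(.is_number(horizon) && horizon >= 1, "'horizon' must be >= 1")
  .assert(.is_number(switch_month) && switch_month >= 1 &&
            switch_month <= horizon + 1,
          "'switch_month' must lie in [1, horizon + 1]")
  ## validates the modifier/setting pairing up front
  apply_modifier(list(behavior = behavior, setting = setting,
                      vendors = vendors), modifier)
  structure(list(setting = setting, pre_policy = pre_policy,
                 post_policy = post_policy, modifier = modifier,
                 n_iterations = as.integer(n_iterations),
                 n_women = as.integer(n_women), seed = as.integer(seed),
                 horizon = as.integer(horizon),
                 switch_month = as.integer(switch_month),
                 population = population, vendors = vendors,
                 behavior = behavior, conversion = conversion,
                 tie_break = match.arg(tie_break)),
            class = "fp_experiment_spec")
}

## Modifier-resolved parameters of a spec.
.resolve_spec <- function(spec) {
  apply_modifier(list(behavior = spec$behavior, setting = spec$setting,
                      vendors = spec$vendors), spec$modifier)
}

#' Run a burn-in/policy-switch experiment
#'
#' For each iteration `i = 1..n_iterations`, seeds the RNG with
#' `seed + i`, draws a fresh population, and simulates `horizon` months:
#' the pre-switch allocation funds the market through month
#' `switch_month - 1` and the post-switch allocation from then on. The
#' sensitivity modifier (if any) is in force from month 1. Because the
#' pre-switch regime is identical across policies, two experiments that
#' share a seed are bit-identical up to the switch and diverge only
#' afterwards.
#'
#' @param spec an [experiment_spec()].
#' @return an `fp_panel`: a data frame with one row per (iteration, month,
#'   woman) holding `iteration`, `month`, `woman_id`, `income_class`,
#'   `quality_sensitivity`, `subgroup`, `protected`, and `vendor` (venue
#'   visited that month, or `"none"`), with the spec and a conservation
#'   audit attached as attributes.
#' @export
#' @examples
#' spec <- experiment_spec("urban", "urban_benchmark",
#'                         n_iterations = 2, n_women = 20, seed = 1)
#' panel <- run_experiment(spec)
#' compute_mcpr(panel[panel$month == 60, ])
run_experiment <- function(spec) {
  .assert(inherits(spec, "fp_experiment_spec"),
          "'spec' must come from experiment_spec()")
  rp <- .resolve_spec(spec)
  n <- spec$n_women
  horizon <- spec$horizon
  chunks <- vector("list", spec$n_iterations)
  audits <- vector("list", spec$n_iterations)
  for (it in seq_len(spec$n_iterations)) {
    set.seed(spec$seed + it)
    pop <- generate_population(n, spec$population)
    state <- new_market_state(pop, rp$setting, rp$vendors, rp$behavior,
                              spec$conversion, spec$pre_policy,
                              tie_break = spec$tie_break)
    protected <- matrix(FALSE, n, horizon)
    vendor <- matrix(0L, n, horizon)
    for (m in seq_len(horizon)) {
      state$allocation <- if (m < spec$switch_month) spec$pre_policy else
        spec$post_policy
      step <- run_month(state, m)
      state <- step$state
      protected[, m] <- step$record$protected
      vendor[, m] <- step$record$vendor
    }
    chunks[[it]] <- data.frame(
      iteration = it,
      month = rep(seq_len(horizon), each = n),
      woman_id = rep(pop$id, horizon),
      income_class = rep(pop$income_class, horizon),
      quality_sensitivity = rep(pop$quality_sensitivity, horizon),
      subgroup = rep(pop$subgroup, horizon),
      protected = as.vector(protected),
      vendor = factor(c("none", "public", "private")[as.vector(vendor) + 1L],
                      levels = c("none", "public", "private"))
    )
    audits[[it]] <- state$audit
  }
  panel <- do.call(rbind, chunks)
  rownames(panel) <- NULL
  attr(panel, "spec") <- spec
  attr(panel, "audit") <- list(
    max_overspend = max(vapply(audits, `[[`, numeric(1), "max_overspend")),
    fp_spend = sum(vapply(audits, `[[`, numeric(1), "fp_spend")),
    revenue = Reduce(`+`, lapply(audits, `[[`, "revenue")),
    quality_range = range(vapply(audits, `[[`, numeric(2), "quality_range")),
    price_range = range(vapply(audits, `[[`, numeric(2), "price_range")),
    public_price_max = max(vapply(audits, `[[`, numeric(1),
                                  "public_price_max"))
  )
  class(panel) <- c("fp_panel", "data.frame")
  panel
}
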