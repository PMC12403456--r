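## The weekly/monthly market loop. Women receive weekly cash they cannot
## save; a woman whose protection has run out comparison-shops over both
## venues and all feasible quantities; a purchase reveals the visited
## venue's true quality; advertising reveals the funded venue's quality to
## a random fraction of the uninformed each month; protection decays by one
## month per month; mCPR is the fraction protected.

#' Service effectiveness as a function of quality
#'
#' One unit of service from a quality-`q` venue averts an unintended
#' pregnancy with probability `e(q) = clip(e_base * (0.5 + 0.1 q), 0, 1)`:
#' even the worst venue is half as effective as the best, and effectiveness
#' rises linearly with the 0-5 quality index. The effectiveness sensitivity
#' modifiers scale `e_base` by 0.75 or 1.25 before this clipping.
#'
#' @param q quality in `[0, 5]` (vectorized).
#' @param bp a [behavior_params()].
#' @return effectiveness fraction(s) in `[0, 1]`, non-decreasing in `q`.
#' @export
effectiveness <- function(q, bp = behavior_params()) {
  .assert(is.numeric(q) && all(is.finite(q)), "'q' must be numeric")
  .assert(all(q >= 0 & q <= .QUALITY_MAX),
          "quality must lie in [0, %d]", .QUALITY_MAX)
  pmin(1, pmax(0, bp$e_base * (0.5 + 0.1 * q)))
}

## Per-unit protective benefit at believed quality qhat for sensitivity
## weight sigma (all vectorized).
.unit_gain <- function(qhat, sigma, bp) {
  bp$acceptance * bp$beta_uip * bp$p0 * effectiveness(qhat, bp) *
    (1 + sigma * qhat / .QUALITY_MAX)
}

## Money cost of reaching vendor v (rural: distance x cost per mile;
## urban: 0).
.travel_cost <- function(x, y, vendor, setting) {
  if (setting$mode == "urban") return(rep(0, length(x)))
  sqrt((x - vendor$x)^2 + (y - vendor$y)^2) * setting$travel_cost_per_mile
}

## Utility-equivalent cost of waiting at vendor v (urban: omega x implied
## hourly wage x wait hours; rural: 0). wage is weekly cash over a 40-hour
## week, so richer women price their time higher.
.wait_cost <- function(weekly_cash, vendor, setting, bp) {
  if (setting$mode == "rural") return(rep(0, length(weekly_cash)))
  bp$omega * (weekly_cash / 40) * vendor$wait_time
}

#' Utility of one candidate purchase plan
#'
#' The satisfaction a woman derives from buying `n` units at vendor `v`
#' this week is
#' \deqn{U = \alpha \log(1 + c - n p_v - t_v) + n A \beta p_0 e(\hat q_v)
#'       (1 + \sigma \hat q_v / 5) - \omega w \cdot \mathrm{wait}_v,}
#' where `c` is this week's cash, `t_v` the travel cost (rural only),
#' `\hat q_v` her believed quality of the venue (her pessimistic prior if
#' uninformed), and `w` her implied hourly wage (urban wait cost only).
#' Buying nothing yields `U = alpha * log(1 + c)`. A plan whose money cost
#' exceeds this week's cash is infeasible and returns `NA`.
#'
#' @param consumer one row of a [generate_population()] data frame.
#' @param vendor an `fp_vendor`, or `NULL` for the no-purchase option.
#' @param n number of units (months of protection) bought; must be 0 iff
#'   `vendor` is `NULL`.
#' @param week_cash cash available this week (defaults to the consumer's
#'   weekly endowment).
#' @param setting a [market_setting()].
#' @param bp a [behavior_params()].
#' @return the utility, or `NA_real_` if the plan is unaffordable.
#' @export
candidate_utility <- function(consumer, vendor = NULL, n = 0L,
                              week_cash = consumer$weekly_cash,
                              setting = market_setting(),
                              bp = behavior_params()) {
  .assert(is.data.frame(consumer) && nrow(consumer) == 1L,
          "'consumer' must be a single-row data frame")
  .assert(.is_number(n) && n >= 0 && n == as.integer(n),
          "'n' must be a non-negative integer")
  .assert_number(week_cash, "week_cash", lower = 0)
  if (is.null(vendor)) {
    .assert(n == 0, "'n' must be 0 for the no-purchase option")
    return(bp$alpha * log1p(week_cash))
  }
  .assert(inherits(vendor, "fp_vendor"), "'vendor' must be an fp_vendor")
  .assert(n >= 1, "'n' must be >= 1 when a vendor is given")
  belief <- if (vendor$sector == "public") consumer$belief_public else
    consumer$belief_private
  qhat <- if (is.na(belief)) bp$prior_quality else belief
  tcost <- .travel_cost(consumer$x, consumer$y, vendor, setting)
  resid <- week_cash - n * vendor$current_price - tcost
  if (resid < -1e-12) return(NA_real_)
  bp$alpha * log1p(max(0, resid)) + n * .unit_gain(qhat, consumer$sigma, bp) -
    .wait_cost(consumer$weekly_cash, vendor, setting, bp)
}

## Vectorized purchase decision for a set of shoppers.
##
## cash, sigma, wage_cash: length-m vectors; qhat, tcost, wcost: m x 2
## matrices (column 1 public, column 2 private); price: length-2 vector of
## current prices. Candidates are evaluated in the fixed order none,
## (public, n = 1..n_max), (private, n = 1..n_max); the running best is
## replaced only on a strict utility improvement or, at a utility tie, a
## strictly lower out-of-pocket spend. Keeping the incumbent on a full tie
## therefore implements the deterministic tie-break: none, then public
## before private, then smaller n. With tie_random = TRUE a full tie
## between the two *vendors* is instead resolved by a fair coin from the
## simulation RNG stream (see the package vignette: with the venues
## exactly indistinguishable, consumers split between them at random, so
## the market is statistically symmetric).
.decide <- function(cash, sigma, qhat, price, tcost, wcost, bp,
                    tie_random = FALSE) {
  m <- length(cash)
  tol <- .FP_TIE_TOL
  best_u <- bp$alpha * log1p(cash)
  best_spend <- numeric(m)
  best_vendor <- integer(m)
  best_n <- integer(m)
  for (v in 1:2) {
    gain_v <- .unit_gain(qhat[, v], sigma, bp)
    for (n in seq_len(bp$n_max)) {
      resid <- cash - n * price[v] - tcost[, v]
      feasible <- resid >= -1e-12
      u <- bp$alpha * log1p(pmax(0, resid)) + n * gain_v - wcost[, v]
      spend <- n * price[v] + tcost[, v]
      better <- feasible & (u > best_u + tol)
      tie <- feasible & !better & (abs(u - best_u) <= tol)
      take <- better | (tie & (spend < best_spend - tol))
      if (tie_random) {
        even <- tie & !take & (abs(spend - best_spend) <= tol) &
          best_vendor > 0L & best_vendor != v
        k <- sum(even)
        if (k > 0L) take[even] <- stats::runif(k) < 0.5
      }
      if (any(take)) {
        best_u[take] <- u[take]
        best_spend[take] <- spend[take]
        best_vendor[take] <- v
        best_n[take] <- n
      }
    }
  }
  list(vendor = best_vendor, n = best_n, utility = best_u,
       spend = best_spend)
}

#' Choose the utility-maximizing purchase plan for one woman
#'
#' Enumerates the no-purchase option and every feasible (vendor, quantity)
#' pair with quantity up to `n_max`, and returns the plan maximizing
#' [candidate_utility()]. Ties are broken deterministically: lower
#' out-of-pocket spend first, then public before private, then the smaller
#' quantity (so the no-purchase plan wins a full tie). With
#' `tie_break = "random"`, an exact tie between the two vendors at equal
#' spend is instead resolved by a fair coin from the current RNG stream,
#' which is how the simulation engine runs (see Details in
#' [run_experiment()]).
#'
#' Only women with zero months of remaining protection shop; callers are
#' expected to enforce that.
#'
#' @param consumer one row of a [generate_population()] data frame.
#' @param vendors named list with `public` and `private` `fp_vendor`s.
#' @param week_cash cash available this week.
#' @param setting a [market_setting()].
#' @param bp a [behavior_params()].
#' @param tie_break `"deterministic"` (default) or `"random"`.
#' @return a list of class `fp_purchase_plan` with `vendor` (`"none"`,
#'   `"public"` or `"private"`), `quantity`, `utility` and `spend`.
#' @export
choose_plan <- function(consumer, vendors,
                        week_cash = consumer$weekly_cash,
                        setting = market_setting(),
                        bp = behavior_params(),
                        tie_break = c("deterministic", "random")) {
  tie_break <- match.arg(tie_break)
  .assert(is.data.frame(consumer) && nrow(consumer) == 1L,
          "'consumer' must be a single-row data frame")
  .assert(is.list(vendors) && all(c("public", "private") %in% names(vendors)),
          "'vendors' must be a list with elements 'public' and 'private'")
  qhat <- cbind(
    ifelse(is.na(consumer$belief_public), bp$prior_quality,
           consumer$belief_public),
    ifelse(is.na(consumer$belief_private), bp$prior_quality,
           consumer$belief_private))
  tcost <- cbind(.travel_cost(consumer$x, consumer$y, vendors$public, setting),
                 .travel_cost(consumer$x, consumer$y, vendors$private, setting))
  wcost <- cbind(.wait_cost(consumer$weekly_cash, vendors$public, setting, bp),
                 .wait_cost(consumer$weekly_cash, vendors$private, setting, bp))
  price <- c(vendors$public$current_price, vendors$private$current_price)
  d <- .decide(week_cash, consumer$sigma, qhat, price, tcost, wcost, bp,
               tie_random = tie_break == "random")
  structure(list(vendor = c("none", "public", "private")[d$vendor + 1L],
                 quantity = d$n, utility = d$utility, spend = d$spend),
            class = "fp_purchase_plan")
}

## ------------------------------------------------------------------------
## Simulation state: one iteration's mutable market.

#' Initialize a simulation state
#'
#' Bundles a population, the two vendors, and the active policy allocation
#' into the mutable state advanced by [run_week()] and [run_month()].
#' Travel and wait costs are precomputed per woman.
#'
#' @param pop a [generate_population()] data frame.
#' @param setting a [market_setting()].
#' @param vp a [vendor_params()].
#' @param bp a [behavior_params()].
#' @param cp a [conversion_params()].
#' @param allocation an [policy_allocation()] funding flow (applied each
#'   month; swap it to switch policy).
#' @param tie_break how exact between-vendor ties are resolved each week;
#'   the engine default is `"random"`.
#' @return a list of class `fp_state`.
#' @export
new_market_state <- function(pop, setting = market_setting(),
                             vp = vendor_params(), bp = behavior_params(),
                             cp = conversion_params(),
                             allocation = named_policy("public_baseline"),
                             tie_break = c("random", "deterministic")) {
  tie_break <- match.arg(tie_break)
  vendors <- make_vendors(setting, vp)
  n <- nrow(pop)
  tcost <- cbind(.travel_cost(pop$x, pop$y, vendors$public, setting),
                 .travel_cost(pop$x, pop$y, vendors$private, setting))
  wcost <- cbind(.wait_cost(pop$weekly_cash, vendors$public, setting, bp),
                 .wait_cost(pop$weekly_cash, vendors$private, setting, bp))
  structure(list(
    pop = pop, vendors = vendors, setting = setting, behavior = bp,
    conversion = cp, allocation = allocation, tie_break = tie_break,
    tcost = tcost, wcost = wcost,
    month_vendor = integer(n),
    audit = list(max_overspend = -Inf, fp_spend = 0,
                 revenue = c(public = 0, private = 0),
                 quality_range = c(Inf, -Inf), price_range = c(Inf, -Inf),
                 public_price_max = 0)
  ), class = "fp_state")
}

## Apply the active allocation's funding flow to both vendors (the
## untargeted vendor reverts to base).
.fund_vendors <- function(state) {
  alloc <- state$allocation
  cp <- state$conversion
  for (s in c("public", "private")) {
    if (s == alloc$target_sector) {
      state$vendors[[s]] <- apply_funding(
        state$vendors[[s]],
        quality_spend = alloc$share_true_quality * alloc$budget,
        price_spend = alloc$share_price_support * alloc$budget,
        cp = cp)
    } else {
      state$vendors[[s]] <- apply_funding(state$vendors[[s]], 0, 0, cp)
    }
  }
  q <- c(state$vendors$public$current_quality,
         state$vendors$private$current_quality)
  p <- c(state$vendors$public$current_price,
         state$vendors$private$current_price)
  state$audit$quality_range <- c(min(state$audit$quality_range[1], q),
                                 max(state$audit$quality_range[2], q))
  state$audit$price_range <- c(min(state$audit$price_range[1], p),
                               max(state$audit$price_range[2], p))
  state$audit$public_price_max <- max(state$audit$public_price_max, p[1])
  state
}

#' Advance the market by one week
#'
#' Every woman receives her weekly cash. Women with zero months of
#' protection choose a purchase plan; buyers pay, add the purchased months
#' to their protection stock, and learn the visited venue's true current
#' quality. Unspent cash is forfeited at the end of the week (there is no
#' saving), so cash never carries over between weeks.
#'
#' @param state an `fp_state` from [new_market_state()].
#' @param week week index within the month (1-4); informational only.
#' @return the updated state.
#' @export
run_week <- function(state, week = 1L) {
  .assert(inherits(state, "fp_state"), "'state' must be an fp_state")
  pop <- state$pop
  shoppers <- which(pop$protection_months == 0L)
  if (length(shoppers) == 0L) return(state)
  bp <- state$behavior
  cash <- pop$weekly_cash[shoppers]
  qhat <- cbind(
    ifelse(is.na(pop$belief_public[shoppers]), bp$prior_quality,
           pop$belief_public[shoppers]),
    ifelse(is.na(pop$belief_private[shoppers]), bp$prior_quality,
           pop$belief_private[shoppers]))
  price <- c(state$vendors$public$current_price,
             state$vendors$private$current_price)
  d <- .decide(cash, pop$sigma[shoppers], qhat, price,
               state$tcost[shoppers, , drop = FALSE],
               state$wcost[shoppers, , drop = FALSE],
               bp, tie_random = state$tie_break == "random")
  bought <- d$vendor > 0L
  if (any(bought)) {
    idx <- shoppers[bought]
    v <- d$vendor[bought]
    n <- d$n[bought]
    pop$protection_months[idx] <- pop$protection_months[idx] + n
    pub <- v == 1L
    if (any(pub))
      pop$belief_public[idx[pub]] <- state$vendors$public$current_quality
    if (any(!pub))
      pop$belief_private[idx[!pub]] <- state$vendors$private$current_quality
    state$month_vendor[idx] <- v
    fp_cost <- n * price[v]
    state$audit$fp_spend <- state$audit$fp_spend + sum(fp_cost)
    state$audit$revenue["public"] <- state$audit$revenue["public"] +
      sum(fp_cost[pub])
    state$audit$revenue["private"] <- state$audit$revenue["private"] +
      sum(fp_cost[!pub])
    state$audit$max_overspend <- max(state$audit$max_overspend,
                                     d$spend[bought] - cash[bought])
  }
  state$pop <- pop
  state
}

#' Advance the market by one month
#'
#' Applies the active allocation's funding flow to the vendors, runs four
#' weeks of [run_week()], then applies the allocation's advertising: a
#' random fraction [advertising_reach()] of the women still uninformed
#' about the funded venue learn its true current quality. Finally the
#' month's protected flags and venue visits are recorded and every
#' positive protection stock is decremented by one month.
#'
#' @param state an `fp_state`.
#' @param month month index; informational only.
#' @return a list with `state` (the updated state) and `record`, a list
#'   with logical `protected` and integer `vendor` (0 none, 1 public,
#'   2 private), one entry per woman.
#' @export
run_month <- function(state, month = 1L) {
  .assert(inherits(state, "fp_state"), "'state' must be an fp_state")
  state$month_vendor <- integer(nrow(state$pop))
  state <- .fund_vendors(state)
  for (w in 1:4) state <- run_week(state, w)

  alloc <- state$allocation
  if (alloc$share_perceived_quality > 0) {
    reach <- advertising_reach(alloc$share_perceived_quality * alloc$budget,
                               state$conversion)
    belief_col <- paste0("belief_", alloc$target_sector)
    uninformed <- which(is.na(state$pop[[belief_col]]))
    if (length(uninformed) > 0L && reach > 0) {
      hit <- uninformed[stats::runif(length(uninformed)) < reach]
      state$pop[[belief_col]][hit] <-
        state$vendors[[alloc$target_sector]]$current_quality
    }
  }

  protected <- state$pop$protection_months > 0L
  record <- list(protected = protected, vendor = state$month_vendor)
  pos <- state$pop$protection_months > 0L
  state$pop$protection_months[pos] <- state$pop$protection_months[pos] - 1L
  list(state = state, record = record)
}

#' Modern contraceptive prevalence rate of a set of panel records
#'
#' The fraction of woman-months protected, optionally restricted to a
#' population segment (which restricts the denominator).
#'
#' @param records an `fp_panel` or any data frame with `protected` and the
#'   segment columns.
#' @param segment `"overall"`, `"low_income"`, `"high_income"`, or one of
#'   the subgroup labels `LI-LQ`, `LI-HQ`, `HI-LQ`, `HI-HQ`.
#' @return fraction in `[0, 1]`.
#' @export
compute_mcpr <- function(records, segment = "overall") {
  .assert(is.data.frame(records) && "protected" %in% names(records),
          "'records' must be a data frame with a 'protected' column")
  records <- .filter_segment(records, segment)
  .assert(nrow(records) > 0L,
          "mCPR is undefined on an empty record set (segment '%s')", segment)
  mean(records$protected)
}

## Restrict panel records to an analysis segment.
.filter_segment <- function(records, segment) {
  .assert(is.character(segment) && length(segment) == 1L,
          "'segment' must be a single string")
  if (segment == "overall") return(records)
  if (segment %in% c("low_income", "high_income")) {
    want <- if (segment == "low_income") "low" else "high"
    .assert("income_class" %in% names(records),
            "records lack an 'income_class' column")
    return(records[records$income_class == want, , drop = FALSE])
  }
  if (segment %in% .SUBGROUP_LEVELS) {
    .assert("subgroup" %in% names(records),
            "records lack a 'subgroup' column")
    return(records[records$subgroup == segment, , drop = FALSE])
  }
  stop(sprintf("unknown segment '%s'; use 'overall', 'low_income', 'high_income', or one of %s",
               segment, paste(.SUBGROUP_LEVELS, collapse = ", ")),
       call. = FALSE)
}
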