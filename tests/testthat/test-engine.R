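test_that("effectiveness is linear in quality, clipped to [0, 1]", {
  expect_equal(effectiveness(5, behavior_params(e_base = 1)), 1)
  expect_equal(effectiveness(0, behavior_params(e_base = 0.95)), 0.475)
  expect_equal(effectiveness(3, behavior_params(e_base = 0.8)), 0.8 * 0.8)
  # a +25% effectiveness modifier pushes past 1 and is clipped
  bp <- behavior_params(e_base = 0.95)
  bp$e_base <- bp$e_base * 1.25
  expect_equal(effectiveness(5, bp), 1)
  q <- seq(0, 5, by = 0.25)
  expect_true(all(diff(effectiveness(q, behavior_params())) >= 0))
  expect_error(effectiveness(5.1), "quality")
  expect_error(effectiveness(-0.1), "quality")
})

test_that("candidate utility matches a hand-computed evaluation", {
  bp <- behavior_params(alpha = 1, beta_uip = 10, acceptance = 0.8,
                        p0 = 0.1, e_base = 0.9, omega = 1.5, n_max = 3,
                        prior_quality = 1.5)
  consumer <- fixture_population()[3, ]   # LI-HQ, sigma 1, weekly cash 10
  consumer$belief_private <- 4
  v <- make_vendor("private", 3, base_price = 2, wait_time = 1)
  # independent arithmetic straight from the definition
  expected <- log(1 + 10 - 2 * 2) +
    2 * (0.8 * 10 * 0.1 * (0.9 * (0.5 + 0.1 * 4)) * (1 + 1 * 4 / 5)) -
    1.5 * (10 / 40) * 1
  expect_equal(candidate_utility(consumer, v, 2, week_cash = 10,
                                 setting = market_setting("urban"), bp = bp),
               expected)
  # the outside option is just log utility of cash
  expect_equal(candidate_utility(consumer, NULL, 0, week_cash = 10, bp = bp),
               log(11))
  # rural travel enters the budget; an unaffordable plan is NA
  rural <- market_setting("rural", travel_cost_per_mile = 10)
  expect_true(is.na(candidate_utility(consumer, v, 2, week_cash = 10,
                                      setting = rural, bp = bp)))
})

test_that("quality-sensitive women value believed quality weakly more", {
  bp <- behavior_params()
  v <- make_vendor("private", 3, base_price = 2, wait_time = 0)
  base <- fixture_population()[1, ]  # sigma 0
  base$belief_private <- 3
  high <- base
  high$sigma <- 1
  u0 <- candidate_utility(base, v, 1, week_cash = 10, bp = bp)
  u1 <- candidate_utility(high, v, 1, week_cash = 10, bp = bp)
  expect_gt(u1, u0)
  # at believed quality 0 the sensitivity weight is inert
  base$belief_private <- 0
  high$belief_private <- 0
  expect_equal(candidate_utility(base, v, 1, week_cash = 10, bp = bp),
               candidate_utility(high, v, 1, week_cash = 10, bp = bp))
})

test_that("choose_plan equals brute-force enumeration on random markets", {
  set.seed(20240917)
  for (i in 1:400) {
    st <- random_state()
    got <- choose_plan(st$consumer, st$vendors, st$cash, st$setting, st$bp)
    want <- oracle_plan(st$consumer, st$vendors, st$cash, st$setting, st$bp)
    expect_identical(got$vendor, want$vendor)
    expect_identical(as.integer(got$quantity), as.integer(want$quantity))
    expect_equal(got$utility, want$utility, tolerance = 1e-12)
  }
})

test_that("degenerate and dominance cases of the purchase decision", {
  bp <- behavior_params()
  # no money, rural, both venues at positive travel cost: only none feasible
  consumer <- fixture_population()[1, ]
  consumer$weekly_cash <- 0
  rural <- market_setting("rural", travel_cost_per_mile = 0.3)
  plan <- choose_plan(consumer, make_vendors(rural), 0, rural, bp)
  expect_identical(plan$vendor, "none")
  expect_identical(as.integer(plan$quantity), 0L)
  # urban, free private with higher believed quality and equal wait wins
  vp <- vendor_params(private_price = 5, public_wait = 2, private_wait = 2)
  urban <- market_setting("urban")
  vendors <- make_vendors(urban, vp)
  vendors$private <- apply_funding(vendors$private, 0, 40,
                                   conversion_params())
  consumer <- fixture_population()[3, ]
  consumer$belief_public <- 2
  consumer$belief_private <- 4
  plan <- choose_plan(consumer, vendors, 10, urban, bp)
  expect_identical(plan$vendor, "private")
})

## A one-woman market she clearly wants to buy in: free-ish private venue
## with known top quality.
.trace_state <- function() {
  pop <- fixture_population()[1, ]  # LI-LQ, weekly cash 10
  pop$belief_public <- 0
  pop$belief_private <- 5
  bp <- behavior_params(beta_uip = 12, omega = 0, n_max = 3,
                        prior_quality = 1.5)
  vp <- vendor_params(public_quality = 0, private_quality = 5,
                      private_price = 1)
  new_market_state(pop, market_setting("urban"), vp, bp,
                   conversion_params(),
                   policy_allocation("private", 0, 1, 0),
                   tie_break = "deterministic")
}

test_that("a week of the loop: purchase, learning, no carry-over", {
  state <- .trace_state()
  state$vendors$private$current_quality <- 4.2
  state <- run_week(state)
  # she buys 3 units at the private vendor and learns its true quality
  expect_equal(state$pop$protection_months, 3L)
  expect_equal(state$pop$belief_private, 4.2)
  expect_equal(unname(state$audit$revenue["private"]), 3)
  expect_equal(state$audit$fp_spend, 3)
  # spend never exceeded the weekly cash
  expect_lte(state$audit$max_overspend, 0)
  # protected women do not shop again
  state2 <- run_week(state, 2)
  expect_equal(state2$audit$fp_spend, state$audit$fp_spend)
})

test_that("a month: one purchase protects the month, stock then decays", {
  state <- .trace_state()
  m1 <- run_month(state, 1)
  expect_true(m1$record$protected)
  expect_equal(m1$record$vendor, 2L)  # private
  expect_equal(m1$state$pop$protection_months, 2L)  # 3 bought, 1 burned
  m2 <- run_month(m1$state, 2)
  expect_true(m2$record$protected)
  expect_equal(m2$record$vendor, 0L)  # no repeat purchase while protected
  m3 <- run_month(m2$state, 3)
  m4 <- run_month(m3$state, 4)
  # stock ran out entering month 4, so she shops again
  expect_equal(m4$record$vendor, 2L)
  expect_equal(m4$state$audit$fp_spend, 6)
})

test_that("advertising informs uninformed women of true current quality", {
  pop <- fixture_population()
  # make every purchase unattractive: long waits everywhere
  bp <- behavior_params(beta_uip = 0.01, omega = 2)
  vp <- vendor_params(public_wait = 8, private_wait = 8,
                      private_quality = 3.7)
  state <- new_market_state(pop, market_setting("urban"), vp, bp,
                            conversion_params(),
                            policy_allocation("private", 1, 0, 0))
  m <- run_month(state, 1)
  expect_false(any(m$record$protected))
  # full reach: every woman now knows the private vendor's true quality
  expect_equal(m$state$pop$belief_private, rep(3.7, 8))
  expect_true(all(is.na(m$state$pop$belief_public)))
})

test_that("mCPR is the protected fraction within the chosen segment", {
  records <- data.frame(
    protected = rep(c(TRUE, FALSE), c(37, 63)),
    income_class = factor(rep(c("low", "high"), 50), c("low", "high")),
    subgroup = factor(rep(c("LI-LQ", "HI-HQ"), 50),
                      c("LI-LQ", "LI-HQ", "HI-LQ", "HI-HQ")))
  expect_equal(compute_mcpr(records), 0.37)
  expect_equal(compute_mcpr(records[records$protected, ]), 1)
  expect_equal(compute_mcpr(records[!records$protected, ]), 0)
  expect_equal(compute_mcpr(records, "low_income"),
               mean(records$protected[records$income_class == "low"]))
  expect_error(compute_mcpr(records[0, ]), "empty")
  expect_error(compute_mcpr(records, "nope"), "unknown segment")
})
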