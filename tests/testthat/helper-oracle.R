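# Independent brute-force oracle for the purchase decision, written
# directly from the utility definition (not via the package's candidate
# machinery): enumerate every (vendor, quantity) candidate, drop the
# unaffordable ones, and take the argmax with ties broken by lower spend,
# then public before private, then smaller quantity.

oracle_utility <- function(consumer, vendor, n, cash, setting, bp) {
  if (is.null(vendor)) return(bp$alpha * log(1 + cash))
  belief <- if (vendor$sector == "public") consumer$belief_public else
    consumer$belief_private
  qhat <- if (is.na(belief)) bp$prior_quality else belief
  travel <- if (setting$mode == "rural")
    sqrt((consumer$x - vendor$x)^2 + (consumer$y - vendor$y)^2) *
      setting$travel_cost_per_mile else 0
  resid <- cash - n * vendor$current_price - travel
  if (resid < -1e-12) return(NA_real_)
  eff <- min(1, max(0, bp$e_base * (0.5 + 0.1 * qhat)))
  gain <- bp$acceptance * bp$beta_uip * bp$p0 * eff *
    (1 + consumer$sigma * qhat / 5)
  wait <- if (setting$mode == "urban")
    bp$omega * (consumer$weekly_cash / 40) * vendor$wait_time else 0
  bp$alpha * log(1 + max(0, resid)) + n * gain - wait
}

oracle_plan <- function(consumer, vendors, cash, setting, bp) {
  tol <- 1e-9
  cand <- data.frame(vendor = "none", n = 0,
                     u = oracle_utility(consumer, NULL, 0, cash, setting, bp),
                     spend = 0, rank_sector = 0)
  for (sector in c("public", "private")) {
    v <- vendors[[sector]]
    travel <- if (setting$mode == "rural")
      sqrt((consumer$x - v$x)^2 + (consumer$y - v$y)^2) *
        setting$travel_cost_per_mile else 0
    for (n in seq_len(bp$n_max)) {
      u <- oracle_utility(consumer, v, n, cash, setting, bp)
      if (!is.na(u))
        cand <- rbind(cand, data.frame(
          vendor = sector, n = n, u = u,
          spend = n * v$current_price + travel,
          rank_sector = if (sector == "public") 1 else 2))
    }
  }
  # lexicographic argmax with tolerance on utility and spend
  best <- cand[1, ]
  for (i in seq_len(nrow(cand))[-1]) {
    ci <- cand[i, ]
    if (ci$u > best$u + tol) best <- ci
    else if (abs(ci$u - best$u) <= tol) {
      if (ci$spend < best$spend - tol) best <- ci
      else if (abs(ci$spend - best$spend) <= tol) {
        if (ci$rank_sector < best$rank_sector) best <- ci
        else if (ci$rank_sector == best$rank_sector && ci$n < best$n)
          best <- ci
      }
    }
  }
  list(vendor = best$vendor, quantity = best$n, utility = best$u)
}

# Random single-consumer market states for property tests.
random_state <- function(mode = c("urban", "rural")) {
  mode <- sample(match.arg(mode, several.ok = TRUE), 1)
  setting <- market_setting(mode, travel_cost_per_mile = runif(1, 0, 0.8))
  bp <- behavior_params(alpha = runif(1, 0.5, 1.5),
                        beta_uip = runif(1, 2, 12),
                        acceptance = runif(1, 0.5, 1),
                        p0 = runif(1, 0.02, 0.15),
                        e_base = runif(1, 0.6, 1),
                        omega = runif(1, 0, 2.5),
                        n_max = sample(1:5, 1),
                        prior_quality = runif(1, 0, 5))
  vp <- vendor_params(public_quality = runif(1, 0, 5),
                      private_quality = runif(1, 0, 5),
                      private_price = runif(1, 0, 12),
                      public_wait = runif(1, 0, 6),
                      private_wait = runif(1, 0, 6))
  vendors <- make_vendors(setting, vp)
  consumer <- data.frame(
    id = 1L, income_class = factor("low", c("low", "high")),
    quality_sensitivity = factor("high", c("low", "high")),
    subgroup = factor("LI-HQ", c("LI-LQ", "LI-HQ", "HI-LQ", "HI-HQ")),
    sigma = runif(1, 0, 2), annual_earnings = 520,
    weekly_cash = runif(1, 0, 60),
    x = runif(1, 0, 33), y = runif(1, 0, 33), protection_months = 0L,
    belief_public = if (runif(1) < 0.4) NA_real_ else runif(1, 0, 5),
    belief_private = if (runif(1) < 0.4) NA_real_ else runif(1, 0, 5))
  consumer$weekly_cash <- runif(1, 0, 60)
  list(consumer = consumer, vendors = vendors, setting = setting, bp = bp,
       cash = consumer$weekly_cash)
}
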