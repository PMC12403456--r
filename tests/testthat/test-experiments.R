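test_that("named policies carry the study allocations", {
  p <- named_policy("urban_benchmark")
  expect_equal(p$target_sector, "private")
  expect_equal(c(p$share_perceived_quality, p$share_true_quality,
                 p$share_price_support), c(0.20, 0.80, 0))
  p <- named_policy("rural_full_price_support")
  expect_equal(c(p$share_perceived_quality, p$share_true_quality,
                 p$share_price_support), c(0.20, 0.40, 0.40))
  expect_equal(named_policy("rural_benchmark")$share_price_support, 0.20)
  expect_equal(named_policy("public_baseline")$share_true_quality, 1)
  for (nm in c("public_baseline", "urban_benchmark", "urban_price_support",
               "rural_benchmark", "rural_full_price_support")) {
    p <- named_policy(nm)
    expect_equal(p$share_perceived_quality + p$share_true_quality +
                   p$share_price_support, 1)
  }
  expect_error(named_policy("robin_hood"), "valid names")
  expect_error(named_policy("urban_benchmark", "rural"), "urban")
})

test_that("allocations validate shares and the public price rule", {
  expect_error(policy_allocation("private", 0.2, 0.2, 0.2), "sum to 1")
  expect_error(policy_allocation("public", 0.2, 0.6, 0.2), "price support")
  expect_silent(policy_allocation("private", 0.2, 0.6, 0.2))
})

test_that("each sensitivity modifier rescales exactly one parameter", {
  base <- list(behavior = behavior_params(), setting = market_setting("urban"),
               vendors = vendor_params())
  expect_identical(apply_modifier(base, "none"), base)
  m <- apply_modifier(base, "longer_wait")
  expect_equal(m$vendors$public_wait, base$vendors$public_wait * 1.25)
  expect_equal(m$vendors$private_wait, base$vendors$private_wait * 1.25)
  expect_identical(m$behavior, base$behavior)
  m <- apply_modifier(base, "fp_resistant")
  expect_equal(m$behavior$acceptance, 0.75)
  expect_identical(m$vendors, base$vendors)
  m <- apply_modifier(base, "uip_indifferent")
  expect_equal(m$behavior$beta_uip, base$behavior$beta_uip * 0.75)
  m <- apply_modifier(base, "consumption_driven")
  expect_equal(m$behavior$alpha, base$behavior$alpha * 1.25)
  m <- apply_modifier(base, "enhanced_effectiveness")
  expect_equal(m$behavior$e_base, base$behavior$e_base * 1.25)
  rural <- list(behavior = behavior_params(),
                setting = market_setting("rural"),
                vendors = vendor_params())
  m <- apply_modifier(rural, "shorter_travel")
  expect_equal(m$setting$travel_cost_per_mile,
               rural$setting$travel_cost_per_mile * 0.75)
  # geometry-specific modifiers are rejected in the other setting
  expect_error(apply_modifier(base, "longer_travel"), "rural")
  expect_error(apply_modifier(rural, "shorter_wait"), "urban")
  expect_error(apply_modifier(base, "bogus"), "unknown modifier")
})

test_that("modifier validity lists follow the geometry", {
  expect_true("longer_wait" %in% modifier_names("urban"))
  expect_false("longer_travel" %in% modifier_names("urban"))
  expect_true("longer_travel" %in% modifier_names("rural"))
  expect_false("shorter_wait" %in% modifier_names("rural"))
})

test_that("a run yields one record per woman per month", {
  spec <- experiment_spec("urban", "urban_benchmark", n_iterations = 1,
                          n_women = 12, seed = 9, horizon = 24,
                          switch_month = 13)
  panel <- run_experiment(spec)
  expect_equal(nrow(panel), 24 * 12)
  expect_equal(as.integer(table(panel$month)), rep(12L, 24))
  expect_setequal(unique(panel$woman_id), 1:12)
  expect_s3_class(panel, "fp_panel")
  expect_named(panel, c("iteration", "month", "woman_id", "income_class",
                        "quality_sensitivity", "subgroup", "protected",
                        "vendor"))
})

test_that("identical spec and seed reproduce the panel byte for byte", {
  spec <- experiment_spec("rural", "rural_benchmark", n_iterations = 2,
                          n_women = 30, seed = 4, horizon = 30,
                          switch_month = 16)
  p1 <- run_experiment(spec)
  p2 <- run_experiment(spec)
  expect_identical(p1, p2)
})

test_that("policy divergence begins only at the switch month", {
  common <- list(setting = "urban", n_iterations = 2, n_women = 25,
                 seed = 21, horizon = 70, switch_month = 61)
  bench <- run_experiment(do.call(experiment_spec,
                                  c(list(post_policy = "urban_benchmark"),
                                    common)))
  alt <- run_experiment(do.call(experiment_spec,
                                c(list(post_policy = "urban_price_support"),
                                  common)))
  pre_cols <- c("iteration", "month", "woman_id", "subgroup", "protected",
                "vendor")
  expect_identical(as.data.frame(bench[bench$month < 61, pre_cols]),
                   as.data.frame(alt[alt$month < 61, pre_cols]))
})

test_that("the audit confirms budget conservation and bounds", {
  spec <- experiment_spec("rural", "rural_full_price_support",
                          n_iterations = 2, n_women = 40, seed = 2,
                          horizon = 40, switch_month = 21)
  panel <- run_experiment(spec)
  audit <- attr(panel, "audit")
  expect_lte(audit$max_overspend, 1e-9)
  expect_equal(audit$fp_spend, sum(audit$revenue))
  expect_gte(audit$quality_range[1], 0)
  expect_lte(audit$quality_range[2], 5)
  expect_gte(audit$price_range[1], 0)
  expect_true(all(panel$protected %in% c(TRUE, FALSE)))
})
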