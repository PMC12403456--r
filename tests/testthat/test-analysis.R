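# A tiny panel with known per-month mCPR patterns for observation tests.
.toy_panel <- function(n_iter = 3, n_women = 8, months = c(51:60, 111:120),
                       post_rate = 0.75) {
  pop <- fixture_population()
  rows <- expand.grid(woman_id = pop$id, month = months,
                      iteration = seq_len(n_iter))
  rows <- rows[order(rows$iteration, rows$month, rows$woman_id), ]
  rows$income_class <- pop$income_class[rows$woman_id]
  rows$quality_sensitivity <- pop$quality_sensitivity[rows$woman_id]
  rows$subgroup <- pop$subgroup[rows$woman_id]
  # pre windows: woman 1-2 protected (25%); post: women 1-6 (75%)
  rows$protected <- ifelse(rows$month > 100,
                           rows$woman_id <= post_rate * n_women,
                           rows$woman_id <= 2)
  rows
}

test_that("observations cover both windows with segment-wise mCPR", {
  panel <- .toy_panel()
  obs <- build_observations(panel)
  expect_equal(nrow(obs), 3 * 20)
  expect_equal(sum(obs$policy == 0), 30)
  expect_equal(unique(obs$mcpr[obs$policy == 0]), 0.25)
  expect_equal(unique(obs$mcpr[obs$policy == 1]), 0.75)
  # a subgroup segment restricts the denominator (2 women per subgroup)
  obs_sg <- build_observations(panel, segment = "LI-LQ")
  expect_equal(unique(obs_sg$mcpr[obs_sg$policy == 0]), 1)
  expect_error(build_observations(panel[panel$month < 100, ]),
               "missing sampling months: 111")
  expect_error(build_observations(panel, segment = "unheard_of"),
               "unknown segment")
})

test_that("beta1 is exactly the difference of window means", {
  obs <- build_observations(.toy_panel())
  fit <- fit_prepost_ols(obs)
  expect_equal(fit$beta1, 0.5, tolerance = 1e-12)
  expect_equal(fit$beta0, 0.25, tolerance = 1e-12)
  expect_equal(fit$se_beta1, 0)
  # property: on noisy data the dummy-OLS identity still holds exactly
  set.seed(99)
  for (i in 1:20) {
    noisy <- data.frame(policy = rep(0:1, each = 15),
                        mcpr = runif(30))
    fit <- fit_prepost_ols(noisy)
    expect_equal(fit$beta1,
                 mean(noisy$mcpr[noisy$policy == 1]) -
                   mean(noisy$mcpr[noisy$policy == 0]),
                 tolerance = 1e-10)
  }
  expect_error(fit_prepost_ols(data.frame(policy = 0, mcpr = 0.5)),
               "both pre")
})

test_that("OLS matches an independent normal-equations solution", {
  # fixed 20-row dataset; oracle solves (X'X)^{-1} X'y and the classical
  # homoskedastic standard error from first principles
  obs <- data.frame(policy = rep(0:1, each = 10),
                    mcpr = c(0.42, 0.40, 0.44, 0.39, 0.41, 0.43, 0.40,
                             0.42, 0.41, 0.38,
                             0.61, 0.63, 0.58, 0.62, 0.64, 0.60, 0.59,
                             0.63, 0.61, 0.62))
  X <- cbind(1, obs$policy)
  beta <- solve(t(X) %*% X, t(X) %*% obs$mcpr)
  resid <- obs$mcpr - X %*% beta
  s2 <- sum(resid^2) / (20 - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  t_stat <- beta[2] / se
  p <- 2 * pt(-abs(t_stat), df = 18)
  fit <- fit_prepost_ols(obs)
  expect_equal(fit$beta0, beta[1], tolerance = 1e-12)
  expect_equal(fit$beta1, beta[2], tolerance = 1e-12)
  expect_equal(fit$se_beta1, se, tolerance = 1e-12)
  expect_equal(fit$p_value, p, tolerance = 1e-12)
  expect_equal(unname(coef(fit)), c(beta))
})

.fake_fit <- function(beta1, se, segment = "overall", beta0 = 0.1,
                      p = 1e-6) {
  structure(list(beta0 = beta0, beta1 = beta1, se_beta1 = se, p_value = p,
                 n_obs = 2000, segment = segment, fit = NULL),
            class = "fp_prepost")
}

test_that("benchmark comparison: z-test, bolding rule, degenerate cases", {
  a <- .fake_fit(0.3968, 0.0028)
  b <- .fake_fit(0.0864, 0.0010)
  cmp <- compare_to_benchmark(a, b)
  # arithmetic check: (39.68 - 8.64) / sqrt(0.28^2 + 0.10^2) on the
  # percentage-point scale
  expect_equal(cmp$z, (39.68 - 8.64) / sqrt(0.28^2 + 0.10^2),
               tolerance = 1e-12)
  expect_gt(cmp$z, 100)
  expect_true(cmp$bold)
  # antisymmetry under swapping, and no bolding for a worse alternative
  rev <- compare_to_benchmark(b, a)
  expect_equal(rev$z, -cmp$z)
  expect_lt(rev$p_value, 0.01)
  expect_false(rev$bold)
  same <- compare_to_benchmark(a, a)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$bold)
  # degenerate zero-standard-error comparisons
  exact_equal <- compare_to_benchmark(.fake_fit(0.2, 0), .fake_fit(0.2, 0))
  expect_equal(exact_equal$z, 0)
  expect_equal(exact_equal$p_value, 1)
  exact_diff <- compare_to_benchmark(.fake_fit(0.3, 0), .fake_fit(0.2, 0))
  expect_equal(exact_diff$z, Inf)
  expect_equal(exact_diff$p_value, 0)
  expect_true(exact_diff$bold)
  expect_error(compare_to_benchmark(a, .fake_fit(0.1, 0.1, "low_income")),
               "different segments")
})

test_that("the results table stars, bolds, and round-trips", {
  bench <- list(overall = .fake_fit(0.0864, 0.0010),
                low_income = .fake_fit(0.0863, 0.0011))
  alt <- list(overall = .fake_fit(0.3968, 0.0028),
              low_income = .fake_fit(0.5955, 0.0036))
  weak <- list(overall = .fake_fit(0.09, 0.001, p = 0.04),
               low_income = .fake_fit(0.07, 0.001, p = 0.2))
  tab <- results_table(list(benchmark = bench, price_support = alt,
                            weak = weak),
                       benchmark = "benchmark")
  expect_equal(nrow(tab), 6)
  expect_false(any(tab$bold[tab$experiment == "benchmark"]))
  expect_true(all(tab$bold[tab$experiment == "price_support"]))
  expect_equal(tab$beta1_pp[tab$experiment == "price_support" &
                              tab$segment == "overall"], 39.68)
  # star codes at the footnote thresholds
  expect_equal(tab$stars[tab$experiment == "benchmark"], c("***", "***"))
  expect_equal(tab$stars[tab$experiment == "weak"], c("**", ""))
  # a single benchmark experiment: one row set, nothing bold
  solo <- results_table(list(benchmark = bench))
  expect_false(any(solo$bold))
  expect_error(results_table(list(a = bench), benchmark = "missing"),
               "benchmark")
  # formatted layout has one row per experiment, one column per segment
  laid <- format_results_table(tab)
  expect_equal(dim(laid), c(3, 2))
  expect_match(laid["price_support", "overall"], "\\*\\*39.68")
  # round trip through delimited text preserves the numbers
  tmp <- tempfile(fileext = ".csv")
  write_results_table(tab, tmp)
  back <- read_results_table(tmp)
  expect_equal(back$beta1_pp, tab$beta1_pp)
  expect_equal(back$bold, tab$bold)
  expect_equal(back$stars, tab$stars)
})
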