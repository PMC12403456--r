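## Parameter constructors. Each returns a validated plain list with a class
## tag so config resolution and printing can dispatch on it. Defaults are the
## frozen calibration of the shipped model; every value is configurable.

#' Population parameters
#'
#' The simulated population is an even 2 x 2 stratification of income class
#' (low/high) and quality sensitivity (low/high). Each woman draws a unique
#' annual earnings level uniformly within her income class band:
#' `earnings * (1 - income_spread)` to `earnings * (1 + income_spread)`.
#' Weekly cash is always annual earnings / 52.
#'
#' @param earnings_low,earnings_high mean annual earnings (money units) of
#'   the low- and high-income classes. Defaults 520 and 2080 give mean
#'   weekly cash of 10 and 40.
#' @param income_spread half-width of the within-class earnings band as a
#'   fraction of the class mean, in `[0, 1)`. `0` collapses each class to a
#'   point mass.
#' @param sigma_low,sigma_high numeric quality-sensitivity weights of the
#'   weak- and strong-preference halves of the population.
#' @param grid_size side length of the square market area (unit cells,
#'   continuous coordinates, origin at the lower-left corner).
#' @return a list of class `fp_population_params`.
#' @export
population_params <- function(earnings_low = 520, earnings_high = 2080,
                              income_spread = 0.5,
                              sigma_low = 0, sigma_high = 1,
                              grid_size = 33) {
  .assert_number(earnings_low, "earnings_low", lower = 1e-12)
  .assert_number(earnings_high, "earnings_high", lower = 1e-12)
  .assert_number(income_spread, "income_spread", lower = 0, upper = 1 - 1e-9)
  .assert_number(sigma_low, "sigma_low", lower = 0)
  .assert_number(sigma_high, "sigma_high", lower = 0)
  .assert_number(grid_size, "grid_size", lower = 1)
  structure(list(earnings_low = earnings_low, earnings_high = earnings_high,
                 income_spread = income_spread,
                 sigma_low = sigma_low, sigma_high = sigma_high,
                 grid_size = grid_size),
            class = "fp_population_params")
}

#' Vendor parameters
#'
#' Base (unfunded) state of the two venues. The public venue is always free;
#' its price is structurally zero and not a parameter. Qualities live on the
#' single 0-5 index. Wait times only matter in the urban geometry, travel
#' only in the rural one.
#'
#' Note the default *base* public quality is low: an unfunded public clinic
#' offers little. Operating quality is flow-sustained by the policy budget
#' ([apply_funding()]), so under the default pre-switch regime (the whole
#' budget on public quality) the public venue runs at 1.0 + 100/40 = 3.5,
#' above the private venue's 2.5 — and falls back to its base when the
#' budget is reallocated.
#'
#' @param public_quality,private_quality base service quality in `[0, 5]`.
#' @param private_price base out-of-pocket price (money units) of one unit
#'   (= one month of protection) at the private venue.
#' @param public_wait,private_wait hours spent per visit (urban setting).
#' @return a list of class `fp_vendor_params`.
#' @export
vendor_params <- function(public_quality = 1, private_quality = 2.5,
                          private_price = 5,
                          public_wait = 4, private_wait = 1) {
  .assert_number(public_quality, "public_quality", 0, 5)
  .assert_number(private_quality, "private_quality", 0, 5)
  .assert_number(private_price, "private_price", lower = 0)
  .assert_number(public_wait, "public_wait", lower = 0)
  .assert_number(private_wait, "private_wait", lower = 0)
  structure(list(public_quality = public_quality,
                 private_quality = private_quality,
                 private_price = private_price,
                 public_wait = public_wait, private_wait = private_wait),
            class = "fp_vendor_params")
}

#' Behavioral parameters
#'
#' Parameters of the weekly purchase decision. A woman with zero months of
#' protection compares keeping her whole weekly cash against buying `n`
#' units at a venue; see [candidate_utility()] for the functional form.
#'
#' @param alpha marginal-utility-of-consumption weight on log residual cash.
#' @param beta_uip disutility weight per expected unintended pregnancy.
#' @param acceptance family-planning acceptance multiplier in `(0, 1]`;
#'   scales the protective benefit of every unit purchased.
#' @param p0 monthly probability of unintended pregnancy when unprotected.
#' @param e_base maximum service effectiveness in `(0, 1]`; see
#'   [effectiveness()].
#' @param omega time-value multiplier: wait hours are priced at
#'   `omega * (weekly cash / 40)` per hour, i.e. at a multiple of the
#'   woman's implied hourly wage, so richer women are more wait-averse.
#' @param n_max maximum units purchasable in one transaction.
#' @param prior_quality believed quality assigned to a venue the woman has
#'   neither visited nor seen advertised. The default equals the private
#'   base quality: an unknown venue is assumed to look like the typical
#'   unfunded market venue. Beliefs are corrected only by a visit or by
#'   truthful advertising, which is the information friction advertising
#'   relieves.
#' @return a list of class `fp_behavior_params`.
#' @export
behavior_params <- function(alpha = 1, beta_uip = 5.5, acceptance = 1,
                            p0 = 0.08, e_base = 0.95, omega = 2,
                            n_max = 3, prior_quality = 2.5) {
  .assert_number(alpha, "alpha", lower = 1e-12)
  .assert_number(beta_uip, "beta_uip", lower = 1e-12)
  .assert_number(acceptance, "acceptance", lower = 1e-12, upper = 1)
  .assert_number(p0, "p0", lower = 1e-12, upper = 1)
  .assert_number(e_base, "e_base", lower = 1e-12, upper = 1)
  .assert_number(omega, "omega", lower = 0)
  .assert(.is_number(n_max) && n_max >= 1 && n_max == as.integer(n_max),
          "'n_max' must be a positive integer")
  .assert_number(prior_quality, "prior_quality", 0, 5)
  structure(list(alpha = alpha, beta_uip = beta_uip, acceptance = acceptance,
                 p0 = p0, e_base = e_base, omega = omega,
                 n_max = as.integer(n_max), prior_quality = prior_quality),
            class = "fp_behavior_params")
}

#' Budget-conversion parameters
#'
#' How policy money turns into quality points, price reductions, and
#' advertising reach. `kappa_price` defaults to the price-support
#' calibration [calibrate_price_support()]: a 40% budget share drives the
#' private price exactly to zero (and 20% halves it).
#'
#' @param budget total policy budget B (money units per month).
#' @param kappa_quality money needed to raise quality by one point.
#' @param kappa_adv money needed for full-population monthly advertising
#'   reach.
#' @param kappa_price money needed to cut the private price by one money
#'   unit, or `NULL` to calibrate from the private base price (the default).
#' @return a list of class `fp_conversion_params`.
#' @export
conversion_params <- function(budget = 100, kappa_quality = 40,
                              kappa_adv = 100, kappa_price = NULL) {
  .assert_number(budget, "budget", lower = 1e-12)
  .assert_number(kappa_quality, "kappa_quality", lower = 1e-12)
  .assert_number(kappa_adv, "kappa_adv", lower = 1e-12)
  if (!is.null(kappa_price)) .assert_number(kappa_price, "kappa_price", lower = 1e-12)
  structure(list(budget = budget, kappa_quality = kappa_quality,
                 kappa_adv = kappa_adv, kappa_price = kappa_price),
            class = "fp_conversion_params")
}

#' Market setting: urban or rural geometry
#'
#' Urban: both venues are co-located at the grid center, travel is free, and
#' wait time is the non-monetary access cost. Rural: the venues sit in
#' opposite corners of the grid, each visit costs
#' `travel_cost_per_mile * Euclidean distance`, and wait time is negligible.
#'
#' @param mode `"urban"` or `"rural"`.
#' @param grid_size side length of the square grid (miles).
#' @param travel_cost_per_mile money per mile traveled to a venue (rural
#'   only; ignored in urban mode).
#' @return a list of class `fp_market_setting`.
#' @export
market_setting <- function(mode = c("urban", "rural"), grid_size = 33,
                           travel_cost_per_mile = 0.5) {
  mode <- match.arg(mode)
  .assert_number(grid_size, "grid_size", lower = 1)
  .assert_number(travel_cost_per_mile, "travel_cost_per_mile", lower = 0)
  structure(list(mode = mode, grid_size = grid_size,
                 travel_cost_per_mile = travel_cost_per_mile),
            class = "fp_market_setting")
}
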