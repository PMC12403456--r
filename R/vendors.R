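## Vendor state and the conversion of policy money into quality, price, and
## advertising reach. Quality bought with policy funds is a flow-sustained
## level, not a cumulative stock: apply_funding always starts from the base
## state, so redirecting the money elsewhere lets quality fall back.

.QUALITY_MAX <- 5

#' Construct a vendor state
#'
#' @param sector `"public"` or `"private"`. The public sector always
#'   charges zero: a non-zero `base_price` for a public vendor is an error.
#' @param base_quality base service quality in `[0, 5]`.
#' @param base_price base out-of-pocket price per unit (money).
#' @param wait_time hours per visit (used in the urban geometry).
#' @param x,y grid location.
#' @return a list of class `fp_vendor` with both base and current quality
#'   and price (current = base until [apply_funding()] is used).
#' @export
make_vendor <- function(sector = c("public", "private"), base_quality,
                        base_price = 0, wait_time = 0, x = 0, y = 0) {
  sector <- match.arg(sector)
  .assert_number(base_quality, "base_quality", 0, .QUALITY_MAX)
  .assert_number(base_price, "base_price", lower = 0)
  if (sector == "public")
    .assert(base_price == 0, "the public vendor's price is always zero")
  .assert_number(wait_time, "wait_time", lower = 0)
  structure(list(sector = sector,
                 base_quality = base_quality, current_quality = base_quality,
                 base_price = base_price, current_price = base_price,
                 wait_time = wait_time, x = x, y = y),
            class = "fp_vendor")
}

#' Place the public and private vendors according to the market geometry
#'
#' Urban: both venues at the grid center (co-located, so travel to either
#' is identical and drops out of the decision). Rural: public in the
#' lower-left corner, private in the upper-right, so half the population is
#' closer to each.
#'
#' @param setting a [market_setting()].
#' @param vp a [vendor_params()].
#' @return named list with elements `public` and `private`, each an
#'   `fp_vendor`.
#' @export
make_vendors <- function(setting = market_setting(), vp = vendor_params()) {
  .assert(inherits(setting, "fp_market_setting"),
          "'setting' must come from market_setting()")
  .assert(inherits(vp, "fp_vendor_params"),
          "'vp' must come from vendor_params()")
  g <- setting$grid_size
  if (setting$mode == "urban") {
    pub_xy <- priv_xy <- c(g / 2, g / 2)
  } else {
    pub_xy <- c(0, 0)
    priv_xy <- c(g, g)
  }
  list(
    public = make_vendor("public", vp$public_quality, 0,
                         wait_time = vp$public_wait,
                         x = pub_xy[1], y = pub_xy[2]),
    private = make_vendor("private", vp$private_quality, vp$private_price,
                          wait_time = vp$private_wait,
                          x = priv_xy[1], y = priv_xy[2])
  )
}

#' Calibrate the price-support conversion rate
#'
#' Fixes `kappa_price` so that spending 40% of the budget on price support
#' drives the private price exactly to zero; consequently a 20% share
#' halves it.
#'
#' @param base_price private base price (> 0).
#' @param budget total policy budget B (> 0).
#' @return `kappa_price = 0.4 * budget / base_price` (money per unit of
#'   price reduction).
#' @export
#' @examples
#' calibrate_price_support(5, 100) # 8: spending 40 cuts the price by 5
calibrate_price_support <- function(base_price, budget) {
  .assert(.is_number(base_price) && base_price > 0,
          "'base_price' must be positive")
  .assert(.is_number(budget) && budget > 0, "'budget' must be positive")
  0.4 * budget / base_price
}

#' Apply a funding flow to a vendor
#'
#' Converts money into service quality and (private sector only) price
#' reduction. Quality is sustained by the flow: the result is always
#' computed from the base state, so re-applying the same flow does not
#' compound, and a zero flow returns the vendor to its base quality and
#' price.
#'
#' @param v an `fp_vendor`.
#' @param quality_spend money per month spent on true quality improvement
#'   (raises quality by `quality_spend / kappa_quality`, clipped to
#'   `[0, 5]`).
#' @param price_spend money per month spent on price support (lowers price
#'   by `price_spend / kappa_price`, floored at 0). Must be 0 for the
#'   public vendor, whose price is already zero.
#' @param cp a [conversion_params()]; a `NULL` `kappa_price` is calibrated
#'   from the vendor's base price via [calibrate_price_support()].
#' @return the vendor with updated `current_quality` and `current_price`.
#' @export
apply_funding <- function(v, quality_spend, price_spend = 0,
                          cp = conversion_params()) {
  .assert(inherits(v, "fp_vendor"), "'v' must be an fp_vendor")
  .assert(inherits(cp, "fp_conversion_params"),
          "'cp' must come from conversion_params()")
  .assert(.is_number(quality_spend) && quality_spend >= 0,
          "'quality_spend' must be non-negative")
  .assert(.is_number(price_spend) && price_spend >= 0,
          "'price_spend' must be non-negative")
  if (v$sector == "public")
    .assert(price_spend == 0,
            "price support cannot target the public vendor (price is already 0)")
  v$current_quality <- min(.QUALITY_MAX,
                           max(0, v$base_quality +
                                 quality_spend / cp$kappa_quality))
  if (price_spend > 0) {
    kp <- cp$kappa_price
    if (is.null(kp)) kp <- calibrate_price_support(v$base_price, cp$budget)
    v$current_price <- max(0, v$base_price - price_spend / kp)
  } else {
    v$current_price <- v$base_price
  }
  v
}

#' Monthly advertising reach bought with a given spend
#'
#' Truthful advertising informs a fraction of the currently uninformed
#' consumers of the funded vendor's true current quality each month. Reach
#' saturates at 1 when the spend covers the whole population.
#'
#' @param adv_spend money per month spent on advertising (>= 0).
#' @param cp a [conversion_params()].
#' @return fraction in `[0, 1]`: `min(1, adv_spend / kappa_adv)`.
#' @export
advertising_reach <- function(adv_spend, cp = conversion_params()) {
  .assert(.is_number(adv_spend) && adv_spend >= 0,
          "'adv_spend' must be non-negative")
  .assert(inherits(cp, "fp_conversion_params"),
          "'cp' must come from conversion_params()")
  min(1, adv_spend / cp$kappa_adv)
}
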