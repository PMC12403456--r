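## Population generation: a stratified 2x2 of income class and quality
## sensitivity, with unique earnings and uniform random grid locations.

.SUBGROUP_LEVELS <- c("LI-LQ", "LI-HQ", "HI-LQ", "HI-HQ")

## Cells receiving the remainder when n %% 4 > 0, chosen so that for every
## even n both the income margin and the sensitivity margin split exactly
## 50/50: extras go to LI-LQ, then HI-HQ, then LI-HQ, then HI-LQ.
.REMAINDER_ORDER <- c("LI-LQ", "HI-HQ", "LI-HQ", "HI-LQ")

.subgroup_cells <- function() {
  data.frame(subgroup = .SUBGROUP_LEVELS,
             income_class = c("low", "low", "high", "high"),
             quality_sensitivity = c("low", "high", "low", "high"),
             stringsAsFactors = FALSE)
}

#' Sizes of the four income x sensitivity cells for a population of size n
#'
#' Base size `n %/% 4` per cell; the `n %% 4` remainder is assigned in the
#' fixed order LI-LQ, HI-HQ, LI-HQ, HI-LQ, which keeps both margins exactly
#' balanced whenever `n` is even. Returned in the canonical cell order
#' LI-LQ, LI-HQ, HI-LQ, HI-HQ.
#'
#' @param n population size.
#' @return named integer vector of length 4 summing to `n`.
#' @export
subgroup_sizes <- function(n) {
  .assert(.is_number(n) && n >= 0 && n == as.integer(n),
          "'n' must be a non-negative integer")
  n <- as.integer(n)
  sizes <- stats::setNames(rep(n %/% 4L, 4L), .SUBGROUP_LEVELS)
  extra <- n %% 4L
  if (extra > 0L) {
    who <- .REMAINDER_ORDER[seq_len(extra)]
    sizes[who] <- sizes[who] + 1L
  }
  sizes
}

#' Generate the simulated consumer population
#'
#' Women are stratified exactly (not Bernoulli-sampled) over the four
#' income x quality-sensitivity cells via [subgroup_sizes()], then the cell
#' labels are randomly permuted over ids. Each woman draws a unique annual
#' earnings level uniformly within her class band, and a uniform random
#' location on the grid. Everyone starts with zero months of protection and
#' no information about either venue's quality.
#'
#' Random draws are taken from the current RNG stream in a fixed order
#' (label permutation, earnings, x, y), so a fixed `seed` reproduces the
#' population byte for byte.
#'
#' @param n population size (non-negative integer).
#' @param params a [population_params()] list.
#' @param seed optional integer; if supplied, `set.seed(seed)` is called
#'   first. Leave `NULL` to draw from the ambient RNG stream (as the
#'   simulation engine does).
#' @return a data frame with one row per woman and columns `id`,
#'   `income_class`, `quality_sensitivity`, `subgroup`, `sigma`,
#'   `annual_earnings`, `weekly_cash`, `x`, `y`, `protection_months`,
#'   `belief_public`, `belief_private` (`NA` = uninformed).
#' @export
#' @examples
#' pop <- generate_population(100, seed = 1)
#' table(pop$subgroup)
generate_population <- function(n, params = population_params(), seed = NULL) {
  .assert(inherits(params, "fp_population_params"),
          "'params' must come from population_params()")
  .assert(.is_number(n) && n == as.integer(n), "'n' must be an integer")
  .assert(n >= 0, "'n' must be non-negative, got %d", as.integer(n))
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)

  cells <- .subgroup_cells()
  sizes <- subgroup_sizes(n)
  subgroup <- rep(cells$subgroup, times = sizes[cells$subgroup])
  if (n > 1L) subgroup <- subgroup[sample.int(n)]

  income_class <- cells$income_class[match(subgroup, cells$subgroup)]
  sensitivity <- cells$quality_sensitivity[match(subgroup, cells$subgroup)]
  mean_earn <- ifelse(income_class == "low", params$earnings_low,
                      params$earnings_high)
  spread <- params$income_spread
  annual <- mean_earn * stats::runif(n, 1 - spread, 1 + spread)
  x <- stats::runif(n, 0, params$grid_size)
  y <- stats::runif(n, 0, params$grid_size)

  data.frame(
    id = seq_len(n),
    income_class = factor(income_class, levels = c("low", "high")),
    quality_sensitivity = factor(sensitivity, levels = c("low", "high")),
    subgroup = factor(subgroup, levels = .SUBGROUP_LEVELS),
    sigma = ifelse(sensitivity == "low", params$sigma_low, params$sigma_high),
    annual_earnings = annual,
    weekly_cash = annual / 52,
    x = x, y = y,
    protection_months = rep(0L, n),
    belief_public = rep(NA_real_, n),
    belief_private = rep(NA_real_, n)
  )
}

#' Subgroup label of a consumer
#'
#' Deterministic 4-way label combining income class and quality
#' sensitivity: `LI`/`HI` for low/high income crossed with `LQ`/`HQ` for
#' low/high quality sensitivity.
#'
#' @param consumer a data frame with columns `income_class` and
#'   `quality_sensitivity` (one or more rows).
#' @return factor with levels `LI-LQ`, `LI-HQ`, `HI-LQ`, `HI-HQ`.
#' @export
subgroup_of <- function(consumer) {
  .assert(is.data.frame(consumer) &&
            all(c("income_class", "quality_sensitivity") %in% names(consumer)),
          "'consumer' needs columns income_class and quality_sensitivity")
  lab <- paste0(ifelse(as.character(consumer$income_class) == "low", "LI", "HI"),
                "-",
                ifelse(as.character(consumer$quality_sensitivity) == "low",
                       "LQ", "HQ"))
  factor(lab, levels = .SUBGROUP_LEVELS)
}
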