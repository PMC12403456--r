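## Pre/post policy analysis: iteration-month mCPR observations from the
## two equilibrium sampling windows, the dummy-variable OLS, the
## benchmark-comparison z-test, and the policy/sensitivity results table.

#' Build iteration-month mCPR observations for the pre/post regression
#'
#' One observation per (iteration, month) in the two sampling windows:
#' months 51-60 (policy dummy 0, late burn-in equilibrium) and months
#' 111-120 (policy dummy 1, post-switch equilibrium). The mCPR of each
#' observation is computed within the requested population segment.
#'
#' @param panel an `fp_panel` from [run_experiment()].
#' @param segment `"overall"`, `"low_income"`, `"high_income"`, or one of
#'   `LI-LQ`, `LI-HQ`, `HI-LQ`, `HI-HQ`.
#' @param pre_window,post_window month vectors defining the two windows.
#' @return data frame of class `fp_observations` with columns `iteration`,
#'   `month`, `policy` (0/1), `mcpr`, `segment`.
#' @export
build_observations <- function(panel, segment = "overall",
                               pre_window = 51:60, post_window = 111:120) {
  .assert(is.data.frame(panel) &&
            all(c("iteration", "month", "protected") %in% names(panel)),
          "'panel' must be a simulation panel data frame")
  wanted <- c(pre_window, post_window)
  missing <- setdiff(wanted, unique(panel$month))
  .assert(length(missing) == 0L,
          "panel is missing sampling months: %s",
          paste(missing, collapse = ", "))
  sub <- .filter_segment(panel[panel$month %in% wanted, , drop = FALSE],
                         segment)
  .assert(nrow(sub) > 0L, "segment '%s' is empty in this panel", segment)
  agg <- stats::aggregate(protected ~ iteration + month, data = sub,
                          FUN = mean)
  obs <- data.frame(iteration = agg$iteration, month = agg$month,
                    policy = as.integer(agg$month %in% post_window),
                    mcpr = agg$protected, segment = segment)
  obs <- obs[order(obs$iteration, obs$month), ]
  rownames(obs) <- NULL
  class(obs) <- c("fp_observations", "data.frame")
  obs
}

#' Fit the pre/post policy regression
#'
#' Ordinary least squares of iteration-month mCPR on an intercept and the
#' policy dummy: `mcpr = beta0 + beta1 * policy + error`. With a dummy
#' regressor, `beta1` is identically the post-minus-pre difference in mean
#' mCPR; its standard error is the classical homoskedastic one and the
#' two-sided p-value comes from the t distribution with `n - 2` degrees of
#' freedom.
#'
#' @param obs an [build_observations()] data frame (any data frame with
#'   `mcpr` and a 0/1 `policy` column works).
#' @return an object of class `fp_prepost` with elements `beta0`, `beta1`,
#'   `se_beta1`, `p_value`, `n_obs`, `segment`, and the underlying `lm`
#'   fit. Supports `print()`, `coef()`, `summary()`, `confint()` and
#'   `residuals()`.
#' @export
fit_prepost_ols <- function(obs) {
  .assert(is.data.frame(obs) && all(c("mcpr", "policy") %in% names(obs)),
          "'obs' must have columns 'mcpr' and 'policy'")
  .assert(length(unique(obs$policy)) == 2L,
          "both pre (policy = 0) and post (policy = 1) observations are required")
  fit <- stats::lm(mcpr ~ policy, data = obs)
  ## summary.lm warns on a perfect fit (zero residuals); that is a
  ## legitimate outcome here (e.g. a saturated segment), not a problem
  ct <- suppressWarnings(stats::coef(summary(fit)))
  structure(list(beta0 = ct["(Intercept)", "Estimate"],
                 beta1 = ct["policy", "Estimate"],
                 se_beta1 = ct["policy", "Std. Error"],
                 p_value = ct["policy", "Pr(>|t|)"],
                 n_obs = nrow(obs),
                 segment = if ("segment" %in% names(obs))
                   as.character(obs$segment[1]) else "overall",
                 fit = fit),
            class = "fp_prepost")
}

#' Compare a policy effect to the benchmark's
#'
#' Two-coefficient z-test on independent runs:
#' `z = (beta1_a - beta1_b) / sqrt(se_a^2 + se_b^2)` with a two-sided
#' normal p-value. The result is marked `bold` (a statistically
#' significant *improvement* over the benchmark) when `p < 0.01` and
#' `beta1_a > beta1_b`; a significantly *worse* effect is never bold. When
#' both standard errors are zero the comparison is degenerate: equal
#' effects give `z = 0, p = 1`; unequal effects are flagged as an
#' infinite-precision difference (`z = +/-Inf`, `p = 0`).
#'
#' @param a the alternative's [fit_prepost_ols()] result.
#' @param b the benchmark's result, for the same segment.
#' @return list of class `fp_benchmark_test` with `z`, `p_value`, `bold`,
#'   and `delta` (`beta1_a - beta1_b`).
#' @export
compare_to_benchmark <- function(a, b) {
  .assert(inherits(a, "fp_prepost") && inherits(b, "fp_prepost"),
          "'a' and 'b' must be fp_prepost fits")
  .assert(identical(a$segment, b$segment),
          "fits are for different segments ('%s' vs '%s')",
          a$segment, b$segment)
  delta <- a$beta1 - b$beta1
  pooled <- sqrt(a$se_beta1^2 + b$se_beta1^2)
  if (pooled == 0) {
    if (delta == 0) {
      z <- 0; p <- 1
    } else {
      z <- sign(delta) * Inf; p <- 0
    }
  } else {
    z <- delta / pooled
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(z = z, p_value = p, bold = p < 0.01 && delta > 0,
                 delta = delta),
            class = "fp_benchmark_test")
}

#' Fit the pre/post regression for several segments of one experiment
#'
#' @param panel an `fp_panel`.
#' @param segments character vector of segments (see
#'   [build_observations()]).
#' @return named list of `fp_prepost` fits.
#' @export
analyze_experiment <- function(panel,
                               segments = c("overall", "low_income")) {
  fits <- lapply(segments, function(s)
    fit_prepost_ols(build_observations(panel, segment = s)))
  stats::setNames(fits, segments)
}

.star_code <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.01) "***" else if (p < 0.05) "**" else if (p < 0.1) "*" else ""
}

#' Assemble the policy/sensitivity results table
#'
#' Rows are experiments, columns are population segments; each cell holds
#' the policy effect `100 * beta1` (percentage points of mCPR) with
#' significance stars (`***` p < 0.01, `**` p < 0.05, `*` p < 0.1), its
#' standard error, and a bold flag where [compare_to_benchmark()] finds a
#' significant improvement over the named benchmark experiment (the
#' benchmark row itself is never bold).
#'
#' @param results named list of experiments, each a named list of
#'   `fp_prepost` fits by segment (as from [analyze_experiment()]); every
#'   experiment must cover the same segments.
#' @param benchmark name of the benchmark experiment in `results`.
#' @return a long data frame of class `fp_results_table` with columns
#'   `experiment`, `segment`, `beta1_pp`, `se_pp`, `p_value`, `stars`,
#'   `bold`, `z_vs_benchmark`, `p_vs_benchmark`. Print it, or lay it out
#'   with [format_results_table()].
#' @export
results_table <- function(results, benchmark = names(results)[1]) {
  .assert(is.list(results) && length(results) >= 1L &&
            !is.null(names(results)) && all(nzchar(names(results))),
          "'results' must be a non-empty named list")
  .assert(benchmark %in% names(results),
          "benchmark experiment '%s' is missing from 'results'", benchmark)
  segments <- names(results[[benchmark]])
  for (nm in names(results))
    .assert(identical(names(results[[nm]]), segments),
            "experiment '%s' does not cover the benchmark's segments", nm)
  rows <- list()
  for (nm in names(results)) {
    for (sg in segments) {
      fit <- results[[nm]][[sg]]
      .assert(inherits(fit, "fp_prepost"),
              "results[['%s']][['%s']] is not an fp_prepost fit", nm, sg)
      if (nm == benchmark) {
        cmp <- list(z = NA_real_, p_value = NA_real_, bold = FALSE)
      } else {
        cmp <- compare_to_benchmark(fit, results[[benchmark]][[sg]])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        experiment = nm, segment = sg,
        beta1_pp = 100 * fit$beta1, se_pp = 100 * fit$se_beta1,
        p_value = fit$p_value, stars = .star_code(fit$p_value),
        bold = cmp$bold, z_vs_benchmark = cmp$z,
        p_vs_benchmark = cmp$p_value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "benchmark") <- benchmark
  class(out) <- c("fp_results_table", "data.frame")
  out
}

#' Lay a results table out as text, one row per experiment
#'
#' Cells read `8.64*** (0.10)`; cells marked as significant improvements
#' over the benchmark are wrapped in `**bold**` markers.
#'
#' @param x an [results_table()].
#' @return character matrix with experiments as rows and segments as
#'   columns.
#' @export
format_results_table <- function(x) {
  .assert(inherits(x, "fp_results_table"),
          "'x' must come from results_table()")
  experiments <- unique(x$experiment)
  segments <- unique(x$segment)
  cells <- matrix("", length(experiments), length(segments),
                  dimnames = list(experiments, segments))
  for (i in seq_len(nrow(x))) {
    cell <- sprintf("%.2f%s (%.2f)", x$beta1_pp[i], x$stars[i], x$se_pp[i])
    if (x$bold[i]) cell <- paste0("**", cell, "**")
    cells[x$experiment[i], x$segment[i]] <- cell
  }
  cells
}
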