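## S3 methods for the package's classed objects.

#' @export
print.fp_purchase_plan <- function(x, ...) {
  if (x$vendor == "none") {
    cat("Purchase plan: no purchase (utility", format(x$utility), ")\n")
  } else {
    cat(sprintf("Purchase plan: %d unit(s) at the %s vendor, spend %.2f, utility %.4f\n",
                x$quantity, x$vendor, x$spend, x$utility))
  }
  invisible(x)
}

#' @export
print.fp_policy <- function(x, ...) {
  cat(sprintf("Policy allocation targeting the %s sector (budget %.0f):\n",
              x$target_sector, x$budget))
  cat(sprintf("  perceived quality (advertising): %3.0f%%\n",
              100 * x$share_perceived_quality))
  cat(sprintf("  true quality improvement:        %3.0f%%\n",
              100 * x$share_true_quality))
  cat(sprintf("  price support:                   %3.0f%%\n",
              100 * x$share_price_support))
  invisible(x)
}

#' @export
print.fp_experiment_spec <- function(x, ...) {
  cat(sprintf("Experiment: %s market, %d iterations x %d women, months 1-%d (switch at %d), modifier '%s', seed %d\n",
              x$setting$mode, x$n_iterations, x$n_women, x$horizon,
              x$switch_month, x$modifier, x$seed))
  invisible(x)
}

#' @export
print.fp_panel <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Simulation panel: %d records (%d iterations x %d months x %d women)\n",
              nrow(x), length(unique(x$iteration)),
              length(unique(x$month)), length(unique(x$woman_id))))
  if (!is.null(spec))
    cat(sprintf("  %s market, modifier '%s', switch at month %d, seed %d\n",
                spec$setting$mode, spec$modifier, spec$switch_month,
                spec$seed))
  cat(sprintf("  overall mCPR: %.3f\n", mean(x$protected)))
  invisible(x)
}

#' Monthly mCPR trajectory of a panel
#'
#' @param panel an `fp_panel`.
#' @param segment population segment (see [compute_mcpr()]).
#' @return data frame with `month` and `mcpr` (averaged over iterations
#'   and women).
#' @export
monthly_mcpr <- function(panel, segment = "overall") {
  sub <- .filter_segment(panel, segment)
  agg <- stats::aggregate(protected ~ month, data = sub, FUN = mean)
  data.frame(month = agg$month, mcpr = agg$protected)
}

#' @export
summary.fp_panel <- function(object, ...) {
  spec <- attr(object, "spec")
  segs <- c("overall", "low_income", "high_income", .SUBGROUP_LEVELS)
  post <- if (!is.null(spec)) spec$switch_month else 61L
  pre_rows <- object$month < post
  out <- data.frame(
    segment = segs,
    mcpr_pre = vapply(segs, function(s)
      compute_mcpr(object[pre_rows, , drop = FALSE], s), numeric(1)),
    mcpr_post = vapply(segs, function(s)
      compute_mcpr(object[!pre_rows, , drop = FALSE], s), numeric(1)))
  rownames(out) <- NULL
  out
}

#' Plot the monthly mCPR trajectory of an experiment
#'
#' Draws the overall mCPR by month with the policy-switch month marked;
#' optionally adds segment trajectories.
#'
#' @param x an `fp_panel`.
#' @param segments segments to overlay (default overall plus the income
#'   classes).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.fp_panel <- function(x, segments = c("overall", "low_income",
                                          "high_income"), ...) {
  traj <- sapply(segments, function(s) monthly_mcpr(x, s)$mcpr)
  months <- sort(unique(x$month))
  graphics::matplot(months, traj, type = "l", lty = 1, lwd = 2,
                    col = seq_along(segments), ylim = c(0, 1),
                    xlab = "month", ylab = "mCPR", ...)
  spec <- attr(x, "spec")
  if (!is.null(spec))
    graphics::abline(v = spec$switch_month - 0.5, lty = 2, col = "grey40")
  graphics::legend("bottomright", legend = segments, lty = 1, lwd = 2,
                   col = seq_along(segments), bty = "n")
  invisible(x)
}

#' @export
print.fp_prepost <- function(x, ...) {
  cat(sprintf("Pre/post mCPR regression (%s segment, n = %d):\n",
              x$segment, x$n_obs))
  cat(sprintf("  beta0 (pre-policy mCPR):    %8.4f\n", x$beta0))
  cat(sprintf("  beta1 (policy effect):      %8.4f (%.1f pp) se = %.4f, p = %s\n",
              x$beta1, 100 * x$beta1, x$se_beta1,
              format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' @export
coef.fp_prepost <- function(object, ...) {
  c("(Intercept)" = object$beta0, policy = object$beta1)
}

#' @export
summary.fp_prepost <- function(object, ...) summary(object$fit, ...)

#' @export
confint.fp_prepost <- function(object, parm = "policy", level = 0.95, ...) {
  stats::confint(object$fit, parm = parm, level = level, ...)
}

#' @export
residuals.fp_prepost <- function(object, ...) stats::residuals(object$fit, ...)

#' @export
print.fp_benchmark_test <- function(x, ...) {
  cat(sprintf("Benchmark comparison: delta beta1 = %.4f (%.1f pp), z = %s, p = %s%s\n",
              x$delta, 100 * x$delta, format(round(x$z, 2)),
              format.pval(x$p_value, digits = 3),
              if (x$bold) " [significant improvement]" else ""))
  invisible(x)
}

#' @export
print.fp_results_table <- function(x, ...) {
  cat(sprintf("Policy effects on mCPR (percentage points; benchmark: %s)\n\n",
              attr(x, "benchmark")))
  print(format_results_table(x), quote = FALSE)
  cat("\n*** p < 0.01, ** p < 0.05, * p < 0.1; (standard error);",
      "**bold** = significant improvement over the benchmark (p < 0.01)\n")
  invisible(x)
}
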