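#' Ordinary least-squares agreement regression
#'
#' Regresses `y` on `x` and reports the quantities used to judge
#' test-retest agreement: `r_squared`, `slope`, `intercept` and a t-based
#' 95 percent confidence interval on the slope.
#'
#' @param x,y Paired metric values of equal length >= 3.
#' @return An object of class `agreement_result` with the regression
#'   fields populated (Bland-Altman fields `NA`; see [bland_altman()]).
#' @export
regress_agreement <- function(x, y) {
  check_pairs(x, y, min_n = 3)
  if (var(x) == 0) {
    stop("`x` has zero variance: regression slope is undefined", call. = FALSE)
  }
  fit <- lm(y ~ x)
  # collinear input (e.g. identical sessions) is a legitimate degenerate
  # case here; lm warns about the perfect fit
  ci <- suppressWarnings(confint(fit, "x", level = 0.95))
  agreement_result(
    r_squared = suppressWarnings(summary(fit)$r.squared),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    slope_ci = c(ci[1], ci[2]),
    n = length(x))
}

#' Bland-Altman agreement statistics
#'
#' Differences `d = y - x` between paired measurements: `bias = mean(d)`,
#' `bias_sd = sd(d)` (sample sd), limits of agreement
#' `bias +/- 1.96 bias_sd`, and the percent bias
#' `100 bias / mean((x + y) / 2)` (grand mean of the pairwise means as the
#' denominator).
#'
#' @param x,y Paired measurements of equal length >= 2.
#' @return An `agreement_result` with the Bland-Altman fields populated.
#' @export
bland_altman <- function(x, y) {
  check_pairs(x, y, min_n = 2)
  d <- y - x
  bias <- mean(d)
  bias_sd <- sd(d)
  agreement_result(
    bias = bias, bias_sd = bias_sd,
    loa = c(lower = bias - 1.96 * bias_sd, upper = bias + 1.96 * bias_sd),
    percent_bias = 100 * bias / mean((x + y) / 2),
    n = length(x))
}

check_pairs <- function(x, y, min_n) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  if (length(x) < min_n) {
    stop(sprintf("at least %d pairs are required", min_n), call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("`x` and `y` must be finite", call. = FALSE)
  }
  invisible(TRUE)
}

agreement_result <- function(r_squared = NA_real_, slope = NA_real_,
                             intercept = NA_real_,
                             slope_ci = c(NA_real_, NA_real_),
                             bias = NA_real_, bias_sd = NA_real_,
                             loa = c(NA_real_, NA_real_),
                             percent_bias = NA_real_, n = NA_integer_) {
  structure(
    list(r_squared = r_squared, slope = slope, intercept = intercept,
         slope_ci = slope_ci, bias = bias, bias_sd = bias_sd, loa = loa,
         percent_bias = percent_bias, n = n),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat("<agreement_result> n =", x$n, "\n")
  if (!is.na(x$r_squared)) {
    cat(sprintf("  r^2 = %.4f, slope = %.4f (95%% CI %.4f-%.4f), intercept = %.4f\n",
                x$r_squared, x$slope, x$slope_ci[1], x$slope_ci[2], x$intercept))
  }
  if (!is.na(x$bias)) {
    cat(sprintf("  bias = %+.3f +/- %.3f mmHg (%.1f%%), LoA [%.3f, %.3f]\n",
                x$bias, x$bias_sd, x$percent_bias, x$loa[1], x$loa[2]))
  }
  invisible(x)
}

merge_agreement <- function(reg, ba) {
  out <- reg
  for (f in c("bias", "bias_sd", "loa", "percent_bias")) out[[f]] <- ba[[f]]
  out
}

#' Between-session agreement of one metric
#'
#' Pairs session A against session B values of the chosen metric across all
#' matched (condition, peak_flow) runs of one flow mode (pulsatile and
#' constant regimens are analysed separately), and returns the combined
#' regression and Bland-Altman result, with session A as `x`.
#'
#' @param harness_table Tibble from [run_harness()].
#' @param metric One of `"peak_drop"`, `"net_drop"`, `"peak_to_peak_drop"`.
#' @param mode `"pulsatile"` or `"constant"`.
#' @return An `agreement_result`.
#' @export
session_comparison <- function(harness_table,
                               metric = c("peak_drop", "net_drop",
                                          "peak_to_peak_drop"),
                               mode = c("pulsatile", "constant")) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  if (metric == "peak_to_peak_drop" && mode == "constant") {
    stop("the peak-to-peak metric is not defined for constant flow",
         call. = FALSE)
  }
  tbl <- harness_table[harness_table$mode == mode, ]
  a <- tbl[tbl$session == "A", c("condition", "peak_flow", metric)]
  b <- tbl[tbl$session == "B", c("condition", "peak_flow", metric)]
  merged <- merge(a, b, by = c("condition", "peak_flow"),
                  suffixes = c("_A", "_B"))
  missing_a <- nrow(b) - nrow(merged)
  missing_b <- nrow(a) - nrow(merged)
  if (nrow(merged) < nrow(a) || nrow(merged) < nrow(b)) {
    stop(sprintf(paste0("unmatched session pairs: %d session-B and %d ",
                        "session-A runs lack a partner"),
                 missing_a, missing_b), call. = FALSE)
  }
  x <- merged[[paste0(metric, "_A")]]
  y <- merged[[paste0(metric, "_B")]]
  merge_agreement(regress_agreement(x, y), bland_altman(x, y))
}

#' Agreement between two pressure-drop metrics
#'
#' Regression of `metric_y` on `metric_x` pooled across all runs of one
#' flow mode (e.g. net on instantaneous peak, expected slope
#' `1 - 2 r (1 - r)`), plus Bland-Altman statistics for the same pairs.
#'
#' @param harness_table Tibble from [run_harness()].
#' @param metric_x,metric_y Column names of the two metrics.
#' @param mode `"pulsatile"` or `"constant"`.
#' @return An `agreement_result`.
#' @export
metric_relation <- function(harness_table, metric_x, metric_y,
                            mode = c("pulsatile", "constant")) {
  mode <- match.arg(mode)
  tbl <- harness_table[harness_table$mode == mode, ]
  x <- tbl[[metric_x]]
  y <- tbl[[metric_y]]
  if (is.null(x) || is.null(y)) {
    stop("metrics not present in the harness table", call. = FALSE)
  }
  keep <- is.finite(x) & is.finite(y)
  merge_agreement(regress_agreement(x[keep], y[keep]),
                  bland_altman(x[keep], y[keep]))
}
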