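# Independent brute-force agreement statistics straight from the
# definitions (normal equations; explicit sums), used to cross-check the
# lm-based implementation.
metric_pair_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- sy / n - slope * sx / n
  resid <- y - intercept - slope * x
  r_squared <- 1 - sum(resid^2) / sum((y - sy / n)^2)
  d <- y - x
  bias <- sum(d) / n
  bias_sd <- sqrt(sum((d - bias)^2) / (n - 1))
  list(slope = slope, intercept = intercept, r_squared = r_squared,
       bias = bias, bias_sd = bias_sd,
       loa = c(bias - 1.96 * bias_sd, bias + 1.96 * bias_sd))
}
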