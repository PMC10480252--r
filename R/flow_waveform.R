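#' Generate the pump flow waveform
#'
#' Pulsatile mode produces a periodic waveform with period `60/heart_rate`:
#' a raised-cosine upstroke to `peak_flow` over the first part of systole
#' (mimicking the progressive-upstroke pump and the rapid emptying of the
#' left ventricle), a raised-cosine decay over the remainder of systole, and
#' zero flow in diastole (the non-return valve clips reverse flow at zero).
#' Constant mode returns `peak_flow` at every sample.
#'
#' @param condition A [flow_condition()].
#' @param sampling_rate Sampling rate, Hz.
#' @param n_samples Number of samples.
#' @param systole_fraction Fraction of the cycle occupied by systole.
#' @param upstroke_fraction Fraction of systole occupied by the upstroke.
#' @return Numeric vector of flow rates, ml/s, length `n_samples`.
#' @examples
#' q <- generate_flow_waveform(flow_condition("pulsatile", 250), 1000, 1600)
#' max(q)  # 250 within one sample of discretisation
#' @export
generate_flow_waveform <- function(condition, sampling_rate, n_samples,
                                   systole_fraction = 0.35,
                                   upstroke_fraction = 0.3) {
  stopifnot(inherits(condition, "flow_condition"))
  n_samples <- as.integer(n_samples)
  if (condition$mode == "constant") {
    return(rep(condition$peak_flow, n_samples))
  }
  t <- (seq_len(n_samples) - 1) / sampling_rate
  period <- 60 / condition$heart_rate
  condition$peak_flow * flow_shape(t %% period, period,
                                   systole_fraction, upstroke_fraction)
}

# Normalised periodic flow shape on [0, period): 0 -> 1 raised-cosine
# upstroke, 1 -> 0 raised-cosine decay, then zero-flow diastole.
flow_shape <- function(tau, period, systole_fraction, upstroke_fraction) {
  t_sys <- systole_fraction * period
  t_up <- upstroke_fraction * t_sys
  q <- numeric(length(tau))
  up <- tau < t_up
  q[up] <- 0.5 * (1 - cos(pi * tau[up] / t_up))
  down <- !up & tau < t_sys
  q[down] <- 0.5 * (1 + cos(pi * (tau[down] - t_up) / (t_sys - t_up)))
  q
}

# Time derivative of the normalised flow shape (analytic, 1/s).
flow_shape_deriv <- function(tau, period, systole_fraction, upstroke_fraction) {
  t_sys <- systole_fraction * period
  t_up <- upstroke_fraction * t_sys
  dq <- numeric(length(tau))
  up <- tau < t_up
  dq[up] <- 0.5 * (pi / t_up) * sin(pi * tau[up] / t_up)
  down <- !up & tau < t_sys
  dq[down] <- -0.5 * (pi / (t_sys - t_up)) *
    sin(pi * (tau[down] - t_up) / (t_sys - t_up))
  dq
}
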