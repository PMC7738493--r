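# Shared internal numerics.

# Orientation difference wrapped to [-90, 90) degrees (axial variable).
.wrap_ori_diff <- function(a, b) {
  ((a - b + 90) %% 180) - 90
}

# Least-squares fit of a fixed single-cycle sine over 360 deg of phase:
# y ~ F0 + A*cos(phi) + B*sin(phi). Returns F0 (mean term), F1
# (peak-to-peak of the fitted sine) and the fitted values.
.sine_fit <- function(phase_deg, y) {
  phi <- phase_deg * pi / 180
  X <- cbind(1, cos(phi), sin(phi))
  cf <- qr.coef(qr(X), y)
  cf[is.na(cf)] <- 0
  list(F0 = cf[1], F1 = 2 * sqrt(cf[2]^2 + cf[3]^2),
       fitted = as.vector(X %*% cf))
}

.gauss <- function(x, mu, sigma) exp(-(x - mu)^2 / (2 * sigma^2))

# Calcium indicator impulse response: difference of exponentials with the
# given rise and decay time constants, sampled on the kernel time base and
# normalized to unit peak.
.ca_impulse <- function(fs = 15, window_s = 1, rise_s = 0.05, decay_s = 0.4) {
  t <- seq(0, window_s - 1 / fs, by = 1 / fs)
  h <- exp(-t / decay_s) - exp(-t / rise_s)
  h / max(h)
}

# Variance explained by fitted values.
.var_explained <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  max(0, min(1, 1 - sum((y - yhat)^2) / sst))
}
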