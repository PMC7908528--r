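# shared fixtures: a nominal ground-truth subject and small oracles

nominal_truth <- function(id = "S01", body_mass = 67.4) {
  subject_truth(
    id,
    profiles = list(jump = fv_profile(1700, 4.5),
                    cycling = fv_profile(600, 3.4),
                    isokinetic = fv_profile(520, 2.6)),
    body_mass = body_mass)
}

# brute-force ordinary least squares via the normal equations (n > 2)
ols_oracle <- function(v, f) {
  X <- cbind(1, v)
  beta <- solve(t(X) %*% X, t(X) %*% f)
  c(intercept = beta[1L], slope = beta[2L])
}

# exact least squares on n = 2: the minimizer interpolates, so the square
# linear system solved by LU (an algorithm independent of the fit path)
# is the oracle
ols2_oracle <- function(v, f) {
  beta <- unname(solve(cbind(1, v), f))
  c(intercept = beta[1L], slope = beta[2L])
}

# steady-state amplitude of a filtered sinusoid, transient excluded
sine_gain <- function(filter_fun, freq, rate, dur = 4, skip_s = 1) {
  t <- seq(0, dur, by = 1 / rate)
  y <- filter_fun(sin(2 * pi * freq * t))
  keep <- t > skip_s & t < dur - skip_s
  max(abs(y[keep]))
}
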