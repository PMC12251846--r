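# shared fixtures built in code

# a small, strictly valid random flow curve (starts at rest, non-negative)
random_curve <- function(n = 10) {
  times <- c(0, cumsum(runif(n - 1, 0.05, 0.5)))
  flows <- c(0, abs(rnorm(n - 1, mean = 20, sd = 10)))
  flow_curve(times, flows)
}

moderate_profile <- function() {
  build_reference_profile(severity_profile_spec("moderate"))
}

severe_profile <- function() {
  build_reference_profile(severity_profile_spec("severe"))
}

# midpoint Riemann sum of the piecewise-linear interpolant, in litres
dense_riemann_volume <- function(curve, n_grid = 2e6) {
  h <- max(curve$times) / n_grid
  mids <- (seq_len(n_grid) - 0.5) * h
  f <- stats::approx(curve$times, curve$flows, xout = mids)$y
  sum(f) * h / 60
}
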