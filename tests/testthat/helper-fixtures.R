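# Build a dissolution_profile from a unit-by-time matrix.
make_profile <- function(units, times, product = "TEST") {
  if (is.vector(units)) units <- matrix(units, nrow = 1)
  dissolution_profile(tibble::tibble(
    product = product,
    unit = rep(seq_len(nrow(units)), each = length(times)),
    time_min = rep(times, nrow(units)),
    release_pct = as.vector(t(units))
  ))
}

# Independent f2 evaluation, written from the defining formula (not via the
# package's helper) for use as an oracle.
oracle_f2 <- function(mu_t, mu_r) {
  p <- length(mu_t)
  50 * log10((1 + sum((mu_t - mu_r)^2) / p)^(-0.5) * 100)
}

# Reference power-law curve anchored at (60 min, 30%) and (480 min, 80%).
ref_curve_params <- function() kp_solve_targets(c(60, 480), c(30, 80))
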