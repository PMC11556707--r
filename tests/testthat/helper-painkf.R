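# Shared fixture builders (everything is generated in code).

# a short cued-impulse schedule
impulse_schedule <- function(n = 60, at = 15, R = 0.8^2) {
  imp <- impulse_at(n, at)
  stimulus_schedule(n, u_tilde = imp, u = imp, R = R)
}

# brute-force fixed-point iteration of the prior-variance recursion;
# independent oracle for steady_state_prior_variance()
iterate_prior_variance <- function(A_hat, Q, R, n_iter = 2e5, tol = 1e-13) {
  Pbar <- Q
  for (i in seq_len(n_iter)) {
    nxt <- A_hat^2 * R * Pbar / (Pbar + R) + Q
    if (abs(nxt - Pbar) < tol * nxt) return(nxt)
    Pbar <- nxt
  }
  Pbar
}

# analytic mean of N(mean, sd^2) truncated to [lo, hi]
tnorm_mean <- function(mean, sd, lo = 0, hi = 10) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

write_tmp_config <- function(lines) {
  path <- withr::local_tempfile(fileext = ".cfg",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
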