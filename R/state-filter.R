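#' Process-noise variance at a step
#'
#' `Q = Q0 + sum(u^2) * Qu`: control input adds uncertainty to the
#' internal-model prediction, on top of the baseline process noise.
#'
#' @param params A [filter_params()] object.
#' @param u Control-input vector of length `m` (the number of control
#'   gains in `params$B_hat`).
#' @return The process-noise variance (scalar).
#' @export
#' @examples
#' process_noise_variance(filter_params(), 0)          # 0.16
#' process_noise_variance(filter_params(B_hat = c(0.7, 1.3)), c(3.7, 0))
process_noise_variance <- function(params, u) {
  if (length(u) != params$m) {
    abort(sprintf("`u` has length %d but the filter has m = %d control gains.",
                  length(u), params$m))
  }
  params$Q0 + sum(u^2) * params$Qu
}

#' Predict the state (expected pain)
#'
#' The prior mean is `xbar = A_hat * x_hat + B_hat %*% u`, optionally plus a
#' sampled process-noise realisation `N(0, Q)` (the model writes the process
#' noise into the prior mean; sampling it reproduces the run-to-run spread
#' of the simulations, switching it off gives the deterministic standard
#' filter). The prior variance is `Pbar = A_hat^2 * P + Q`.
#'
#' @param state List with posterior mean `x_hat`, variance `P`, and step
#'   index `k` (as returned by [update_state()]).
#' @param params A [filter_params()] object.
#' @param u Control-input vector of length `m`.
#' @param sample_process_noise Draw the noise realisation into the prior
#'   mean? Default `FALSE` here; the scenario engines default to `TRUE`.
#' @param noise Optional pre-drawn standard-normal deviate used when
#'   sampling (so that noise streams stay independent); drawn from the
#'   current RNG if `NULL`.
#' @return A list with `xbar_hat`, `Pbar`, and `Q`.
#' @export
#' @examples
#' st <- list(x_hat = 5, P = 1, k = 0)
#' predict_state(st, filter_params(A_hat = 0.8), u = 0)
predict_state <- function(state, params, u, sample_process_noise = FALSE,
                          noise = NULL) {
  Q <- process_noise_variance(params, u)
  xbar <- params$A_hat * state$x_hat + sum(params$B_hat * u)
  if (isTRUE(sample_process_noise)) {
    eps <- if (is.null(noise)) rnorm(1) else noise
    xbar <- xbar + eps * sqrt(Q)
  }
  list(xbar_hat = xbar, Pbar = params$A_hat^2 * state$P + Q, Q = Q)
}

#' Update the state (perceived pain)
#'
#' Fuses the prior with sensory input: `K = Pbar / (Pbar + R)`,
#' `x_hat = xbar + K * (z - xbar)`, `P = (1 - K) * Pbar`. The posterior mean
#' is a convex combination of prior mean and observation, and the posterior
#' variance is always below the prior variance.
#'
#' @param prior A prior as returned by [predict_state()] (needs `xbar_hat`
#'   and `Pbar`).
#' @param z Sensory input (scalar).
#' @param R Sensory-noise variance (`> 0`).
#' @param k Step index stored on the result (default `NA`).
#' @return A list with `x_hat`, `P`, `K`, and `k`.
#' @export
#' @examples
#' update_state(list(xbar_hat = 2, Pbar = 0.64), z = 4, R = 0.64)$x_hat # 3
update_state <- function(prior, z, R, k = NA_integer_) {
  if (!is.numeric(R) || R <= 0) abort("`R` must be > 0.")
  K <- prior$Pbar / (prior$Pbar + R)
  x_hat <- prior$xbar_hat + K * (z - prior$xbar_hat)
  list(x_hat = x_hat, P = (1 - K) * prior$Pbar, K = K, k = k)
}

#' Steady-state prior variance (scalar Riccati fixed point)
#'
#' The unique positive solution of `Pbar = A_hat^2 * R * Pbar / (Pbar + R)
#' + Q`, i.e. the fixed point the iterated prior variance converges to
#' under constant `A_hat`, `Q`, `R`. Solved in closed form from the
#' quadratic `Pbar^2 + (R - A_hat^2 R - Q) Pbar - Q R = 0`; serves as the
#' convergence oracle for the filter recursions.
#'
#' @param A_hat Persistence coefficient (`>= 0`).
#' @param Q Process-noise variance (`> 0`).
#' @param R Sensory-noise variance (`> 0`).
#' @return The steady-state prior variance (scalar, `>= Q`).
#' @export
#' @examples
#' steady_state_prior_variance(0, Q = 0.16, R = 0.64)   # Q
#' steady_state_prior_variance(1, Q = 0.16, R = 0.64)
steady_state_prior_variance <- function(A_hat, Q, R) {
  stopifnot(A_hat >= 0, Q > 0, R > 0)
  b <- R - A_hat^2 * R - Q
  (-b + sqrt(b^2 + 4 * Q * R)) / 2
}

#' Run the single-layer filter over a schedule
#'
#' Filters a full run: for each step, predict from the internal model,
#' then fuse with the sensory input for that step. Sensory input can be
#' supplied directly (column `z` via the `z` argument) or is drawn from the
#' world model (truncated Gaussian around the simulated tissue damage).
#'
#' @param schedule A [stimulus_schedule()] tibble.
#' @param params A [filter_params()] object (its `R` is overridden by the
#'   schedule's per-step `R` column).
#' @param z Optional sensory-input vector (length `nrow(schedule)`). If
#'   `NULL`, tissue damage is simulated with `world` and `z` is drawn from
#'   the truncated Gaussian under the replicate's sensory noise stream.
#' @param world A [world_params()] object used when `z` is `NULL`.
#' @param seed,replicate Seed and replicate index defining the noise
#'   streams.
#' @param sample_process_noise Sample the process-noise realisation into
#'   the prior mean (default `TRUE`, matching the stochastic simulations).
#' @param x_true Optional externally imposed tissue-damage trajectory
#'   (overrides the world recursion; used by the offset-analgesia plateau
#'   profile).
#' @return A tibble with one row per step: `step`, `x` (true damage), `z`,
#'   `Q`, `xbar_hat`, `Pbar`, `K`, `x_hat`, `P`.
#' @export
#' @examples
#' sch <- stimulus_schedule(50, u_tilde = impulse_at(50, 10), u = impulse_at(50, 10))
#' run_filter(sch, filter_params(A_hat = 1), seed = 1)
run_filter <- function(schedule, params, z = NULL, world = world_params(),
                       seed = 1, replicate = 1,
                       sample_process_noise = TRUE, x_true = NULL) {
  n <- nrow(schedule)
  u <- schedule_u(schedule)
  if (ncol(u) != params$m) {
    abort(sprintf("schedule has m = %d control channels but the filter has %d gains.",
                  ncol(u), params$m))
  }
  Rvec <- schedule$R
  if (is.null(x_true)) x_true <- simulate_world(schedule$u_tilde, world, x0 = 0)
  if (is.null(z)) {
    z <- with_stream_seed(
      stream_seed(seed, replicate, "sensory"),
      sample_sensory(x_true, H = world$H, R = Rvec, bounds = world$bounds)
    )
  }
  w <- if (sample_process_noise) {
    with_stream_seed(stream_seed(seed, replicate, "process"), rnorm(n))
  }
  kf_core(params, u, Rvec, z, w = w, x_true = x_true)
}

# Deterministic single-layer engine: all stochastic inputs pre-drawn.
# `w` holds standard-normal process deviates (NULL = noise off).
kf_core <- function(params, u, Rvec, z, w = NULL, x_true = NULL) {
  n <- length(z)
  A <- params$A_hat
  B <- params$B_hat
  x_hat <- params$x0
  P <- params$P0
  out <- matrix(NA_real_, n, 7,
                dimnames = list(NULL, c("Q", "xbar_hat", "Pbar", "K",
                                        "x_hat", "P", "z")))
  for (k in seq_len(n)) {
    uk <- u[k, ]
    Q <- params$Q0 + sum(uk^2) * params$Qu
    xbar <- A * x_hat + sum(B * uk)
    if (!is.null(w)) xbar <- xbar + w[k] * sqrt(Q)
    Pbar <- A^2 * P + Q
    K <- Pbar / (Pbar + Rvec[k])
    x_hat <- xbar + K * (z[k] - xbar)
    P <- (1 - K) * Pbar
    out[k, ] <- c(Q, xbar, Pbar, K, x_hat, P, z[k])
  }
  res <- tibble::as_tibble(out)
  res$step <- seq_len(n)
  res$x <- if (is.null(x_true)) NA_real_ else x_true
  res[, c("step", "x", "z", "Q", "xbar_hat", "Pbar", "K", "x_hat", "P")]
}
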