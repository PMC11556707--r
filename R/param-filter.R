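#' Predict the internal-model parameters
#'
#' The parameter prior is a random walk: `pbar = p` (optionally plus a draw
#' from `N(0, Q_p)`), with covariance `Pbar_p = P_p + Q_p`. The diagonal
#' `Q_p` both injects drift into the internal model and sets how strongly
#' prediction errors update it.
#'
#' @param state List with parameter vector `p_hat` and covariance `P_p`.
#' @param Q_p Diagonal of the internal-model noise covariance (vector of
#'   length `length(p_hat)`).
#' @param sample_noise Sample the random-walk increment into `pbar`?
#' @param noise Optional pre-drawn standard-normal vector used when
#'   sampling.
#' @return A list with `pbar_hat` and `Pbar_p`.
#' @export
#' @examples
#' st <- list(p_hat = c(0.8, 0.6), P_p = diag(2))
#' predict_params(st, Q_p = rep(0.002^2, 2))
predict_params <- function(state, Q_p, sample_noise = FALSE, noise = NULL) {
  pbar <- state$p_hat
  if (isTRUE(sample_noise)) {
    eps <- if (is.null(noise)) rnorm(length(pbar)) else noise
    pbar <- pbar + eps * sqrt(Q_p)
  }
  list(pbar_hat = pbar, Pbar_p = state$P_p + diag(Q_p, length(Q_p)))
}

#' Parameter-to-state observation row
#'
#' The mapping from parameter space to state space is the sensitivity of
#' the posterior pain to the parameters:
#' `Hp = (1 - K) * c(x_hat_prev, u)`. When `K = 1` the posterior ignores
#' the prior entirely and the parameters are unobservable (`Hp = 0`).
#'
#' @param K State Kalman gain in `[0, 1]`.
#' @param x_hat_prev Posterior pain estimate of the previous step.
#' @param u Control-input vector of length `m`.
#' @return Numeric row vector of length `1 + m`.
#' @export
#' @examples
#' compute_Hp(0.5, x_hat_prev = 4, u = 0) # c(2, 0)
compute_Hp <- function(K, x_hat_prev, u) {
  stopifnot(K >= 0, K <= 1)
  (1 - K) * c(x_hat_prev, u)
}

#' Update the internal-model parameters from a prediction error
#'
#' Standard Kalman update on the parameter vector with scalar innovation
#' `e_hat = x_hat - xbar_hat` whose variance is `R_p = P + Pbar` (the sum
#' of the covariances of the two terms forming the error):
#' `K_p = Pbar_p Hp' / (Hp Pbar_p Hp' + R_p)`, `p = pbar + K_p * e_hat`.
#' The covariance update is scaled by the state gain,
#' `P_p = (I - K * K_p Hp) Pbar_p = Pbar_p - K (Pbar_p Hp')(Hp Pbar_p)/S`
#' (the symmetric, positive-semidefinite-preserving expansion; left
#' multiplication by the covariance instead breaks PSD under the
#' gain scaling): with infinite sensory noise (`K -> 0`)
#' there is no reliable input to inform the parameter estimate, so its
#' covariance must not collapse toward zero. Setting `legacy = TRUE` uses
#' the unscaled update `P_p = Pbar_p (I - K_p Hp)`, which does collapse;
#' it is provided for comparison only. The result is symmetrised to
#' suppress floating-point asymmetry.
#'
#' @param pbar_hat,Pbar_p Parameter prior (from [predict_params()]).
#' @param Hp Observation row from [compute_Hp()].
#' @param e_hat Prediction error `x_hat - xbar_hat`.
#' @param R_p Error variance `P + Pbar` (`> 0`).
#' @param K State Kalman gain used as the covariance scaling factor.
#' @param legacy Use the unscaled covariance update.
#' @return A list with `p_hat`, `P_p`, and the gain column `K_p`.
#' @export
#' @examples
#' update_params(1, matrix(1), Hp = 1, e_hat = 2, R_p = 1, K = 1)
update_params <- function(pbar_hat, Pbar_p, Hp, e_hat, R_p, K,
                          legacy = FALSE) {
  if (!is.numeric(R_p) || R_p <= 0) abort("`R_p` must be > 0.")
  d <- length(pbar_hat)
  Pbar_p <- matrix(Pbar_p, d, d)
  v <- as.numeric(Pbar_p %*% Hp)
  S <- sum(Hp * v) + R_p
  K_p <- v / S
  p_hat <- pbar_hat + K_p * e_hat
  scale <- if (legacy) 1 else K
  # (I - scale * K_p Hp) %*% Pbar_p = Pbar_p - scale * v v' / S: the
  # symmetric, PSD-preserving expansion of the gain-scaled update
  P_p <- Pbar_p - (scale / S) * tcrossprod(v)
  P_p <- (P_p + t(P_p)) / 2
  list(p_hat = p_hat, P_p = P_p, K_p = K_p)
}

#' Hierarchical state prediction
#'
#' As [predict_state()] but with time-varying parameters supplied by the
#' parameter filter, and with the parameter-uncertainty term
#' `Hp %*% P_p %*% t(Hp)` added to the prior variance. The `Hp` entering
#' the variance term is the one computed at the end of the previous step
#' (the fresh `Hp` needs the current gain, which needs this variance; the
#' gain varies slowly, so the one-step lag is benign — a sensitivity check
#' is part of the test suite).
#'
#' @param state List with `x_hat` and `P` (previous posterior).
#' @param pbar_hat Parameter vector `c(A_hat, B_hat...)` used at this step.
#' @param Pbar_p Covariance of those parameters.
#' @param params A [hier_params()] object (supplies `Q0`, `Qu`).
#' @param Hp_prev Lagged observation row (zero vector at the first step).
#' @param u Control-input vector.
#' @param sample_process_noise,noise As in [predict_state()].
#' @return A list with `xbar_hat`, `Pbar`, and `Q`.
#' @export
hier_predict_state <- function(state, pbar_hat, Pbar_p, params, Hp_prev, u,
                               sample_process_noise = FALSE, noise = NULL) {
  Q <- params$Q0 + sum(u^2) * params$Qu
  A <- pbar_hat[1]
  B <- pbar_hat[-1]
  xbar <- A * state$x_hat + sum(B * u)
  if (isTRUE(sample_process_noise)) {
    eps <- if (is.null(noise)) rnorm(1) else noise
    xbar <- xbar + eps * sqrt(Q)
  }
  Pbar <- A^2 * state$P + Q + drop(Hp_prev %*% Pbar_p %*% Hp_prev)
  list(xbar_hat = xbar, Pbar = Pbar, Q = Q)
}

#' One full hierarchical step
#'
#' Executes, in order: parameter prior, state prior (lagged `Hp` in the
#' variance term), state update (yielding the gain `K`), fresh
#' `Hp = (1 - K) c(x_hat_prev, u)`, prediction error
#' `e_hat = x_hat - xbar_hat` with variance `R_p = P + Pbar`, and the
#' parameter update. The prediction error thus acts as the bottom-up input
#' to the parameter filter, and the updated parameters are in force from
#' the next state prediction on.
#'
#' @param z Sensory input at this step.
#' @param u Control-input vector.
#' @param R Sensory-noise variance at this step.
#' @param fstate List with `x_hat`, `P` (state posterior of the previous
#'   step).
#' @param pstate List with `p_hat`, `P_p`, and lagged `Hp`.
#' @param params A [hier_params()] object.
#' @param sample_process_noise,sample_param_noise Noise-sampling flags.
#' @param process_noise,param_noise Optional pre-drawn standard-normal
#'   deviates for the two noise sources.
#' @return A list with the updated `fstate`, `pstate`, and a one-row
#'   tibble `record` logging all intermediates.
#' @export
hier_step <- function(z, u, R, fstate, pstate, params,
                      sample_process_noise = FALSE,
                      sample_param_noise = FALSE,
                      process_noise = NULL, param_noise = NULL) {
  pp <- predict_params(pstate, params$Q_p, sample_noise = sample_param_noise,
                       noise = param_noise)
  sp <- hier_predict_state(fstate, pp$pbar_hat, pp$Pbar_p, params,
                           Hp_prev = pstate$Hp, u = u,
                           sample_process_noise = sample_process_noise,
                           noise = process_noise)
  up <- update_state(sp, z, R)
  Hp <- compute_Hp(up$K, fstate$x_hat, u)
  e_hat <- up$x_hat - sp$xbar_hat
  R_p <- up$P + sp$Pbar
  pu <- update_params(pp$pbar_hat, pp$Pbar_p, Hp, e_hat, R_p, up$K,
                      legacy = isTRUE(params$legacy_pp_update))
  record <- tibble::tibble(
    z = z, Q = sp$Q, xbar_hat = sp$xbar_hat, Pbar = sp$Pbar,
    K = up$K, x_hat = up$x_hat, P = up$P,
    e_hat = e_hat, R_p = R_p,
    p_hat = list(pu$p_hat), K_p = list(pu$K_p),
    Pp_diag = list(diag(pu$P_p))
  )
  list(
    fstate = list(x_hat = up$x_hat, P = up$P),
    pstate = list(p_hat = pu$p_hat, P_p = pu$P_p, Hp = Hp),
    record = record
  )
}

#' Run the hierarchical filter over a schedule
#'
#' As [run_filter()] but with the parameter filter in the loop. With
#' `Q_p = 0` and `P_p0 = 0` the run reproduces the single-layer trajectory
#' bit-exactly under matched noise streams.
#'
#' @inheritParams run_filter
#' @param params A [hier_params()] object.
#' @param sample_param_noise Sample the parameter random-walk increments
#'   (default `TRUE`).
#' @param P_init Optional initial posterior state variance override (e.g.
#'   `P = 1` at a nerve injury).
#' @return A tibble with one row per step: the single-layer columns plus
#'   `e_hat`, `R_p`, the parameter estimates `A_hat`, `b1..bm`, the gain
#'   components `Kp_A`, `Kp_b1..`, and the covariance diagonal `Pp_A`,
#'   `Pp_b1..`.
#' @export
#' @examples
#' sch <- stimulus_schedule(50, R = 800^2)
#' run_hier_filter(sch, hier_params(P0 = 1, P_p0 = diag(2)), seed = 1)
run_hier_filter <- function(schedule, params, z = NULL,
                            world = world_params(), seed = 1, replicate = 1,
                            sample_process_noise = TRUE,
                            sample_param_noise = TRUE,
                            x_true = NULL, P_init = NULL) {
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
  d <- 1L + params$m
  ns <- draw_noise_streams(seed, replicate, n, d)
  w <- if (sample_process_noise) ns$process
  wp <- if (sample_param_noise) ns$param
  hkf_core(params, u, Rvec, z, w = w, wp = wp, x_true = x_true,
           P_init = P_init)
}

# Deterministic hierarchical engine. `w` (length n) and `wp` (n x d) hold
# standard-normal deviates; NULL switches that noise source off.
hkf_core <- function(params, u, Rvec, z, w = NULL, wp = NULL, x_true = NULL,
                     P_init = NULL) {
  n <- length(z)
  d <- 1L + params$m
  Qp_diag <- params$Q_p
  Qp <- diag(Qp_diag, d)
  sqrt_Qp <- sqrt(Qp_diag)
  legacy <- isTRUE(params$legacy_pp_update)

  x_hat <- params$x0
  P <- if (is.null(P_init)) params$P0 else P_init
  p <- c(params$A_hat, params$B_hat)
  Pp <- params$P_p0
  Hp_lag <- numeric(d)

  base <- matrix(NA_real_, n, 9,
                 dimnames = list(NULL, c("Q", "xbar_hat", "Pbar", "K",
                                         "x_hat", "P", "e_hat", "R_p", "z")))
  p_log <- matrix(NA_real_, n, d)
  Kp_log <- matrix(NA_real_, n, d)
  Pp_log <- matrix(NA_real_, n, d)

  for (k in seq_len(n)) {
    uk <- u[k, ]
    # parameter prior (noise drawn into the parameters actually used)
    pbar <- p
    if (!is.null(wp)) pbar <- pbar + wp[k, ] * sqrt_Qp
    Pbar_p <- Pp + Qp
    # state prior with lagged Hp in the variance term
    Q <- params$Q0 + sum(uk^2) * params$Qu
    xbar <- pbar[1] * x_hat + sum(pbar[-1] * uk)
    if (!is.null(w)) xbar <- xbar + w[k] * sqrt(Q)
    Pbar <- pbar[1]^2 * P + Q + drop(Hp_lag %*% Pbar_p %*% Hp_lag)
    # state update
    K <- Pbar / (Pbar + Rvec[k])
    x_new <- xbar + K * (z[k] - xbar)
    P_new <- (1 - K) * Pbar
    # parameter update from the prediction error
    Hp <- (1 - K) * c(x_hat, uk)
    e_hat <- x_new - xbar
    R_p <- P_new + Pbar
    v <- as.numeric(Pbar_p %*% Hp)
    S <- sum(Hp * v) + R_p
    K_p <- v / S
    p <- pbar + K_p * e_hat
    scale <- if (legacy) 1 else K
    Pp <- Pbar_p - (scale / S) * tcrossprod(v)
    Pp <- (Pp + t(Pp)) / 2

    x_hat <- x_new
    P <- P_new
    Hp_lag <- Hp
    base[k, ] <- c(Q, xbar, Pbar, K, x_new, P_new, e_hat, R_p, z[k])
    p_log[k, ] <- p
    Kp_log[k, ] <- K_p
    Pp_log[k, ] <- diag(Pp)
  }

  res <- tibble::as_tibble(base)
  res$step <- seq_len(n)
  res$x <- if (is.null(x_true)) NA_real_ else x_true
  pn <- c("A_hat", paste0("b", seq_len(params$m)))
  for (j in seq_len(d)) {
    res[[pn[j]]] <- p_log[, j]
    res[[paste0("Kp_", pn[j])]] <- Kp_log[, j]
    res[[paste0("Pp_", pn[j])]] <- Pp_log[, j]
  }
  res[, c("step", "x", "z", "Q", "xbar_hat", "Pbar", "K", "x_hat", "P",
          "e_hat", "R_p", pn, paste0("Kp_", pn), paste0("Pp_", pn))]
}
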