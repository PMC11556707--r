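#' Perception-filter parameters
#'
#' Constructs the internal-model and noise constants of the single-layer
#' perception filter. The perceived pain is the posterior estimate of a
#' latent tissue-damage state: at each step the internal model produces the
#' expected pain `xbar = A_hat * xhat_prev + B_hat %*% u` with process-noise
#' variance `Q = Q0 + sum(u^2) * Qu`, and the posterior fuses that prior with
#' sensory input `z` through the Kalman gain `K = Pbar / (Pbar + R)`.
#'
#' Defaults are the simulation defaults of the model: `A_hat = 0.8`,
#' `B_hat = 0.6` per control channel, `H = 1`, `R = 0.8^2`, `Q0 = 0.4^2`,
#' `Qu = 0.4^2`, `P0 = 1e6`. Variances are on the squared 11-point pain
#' scale.
#'
#' @param A_hat Estimated pain-persistence coefficient (unitless, `>= 0`).
#'   Values below 1 mean pain is expected to diminish, above 1 to worsen.
#' @param B_hat Numeric vector of estimated control gains, one per control
#'   channel (cue).
#' @param H Observation mapping from state to sensory input (default 1).
#' @param R Sensory-noise variance (`> 0`).
#' @param Q0 Baseline process-noise variance (`>= 0`).
#' @param Qu Control-dependent process-noise coefficient (`>= 0`); the
#'   process-noise variance at a step is `Q0 + sum(u^2) * Qu`.
#' @param P0 Initial posterior variance (`> 0`).
#' @param x0 Initial posterior mean (default 0; with the default `P0 = 1e6`
#'   the first update is dominated by the sensory input, so this choice is
#'   immaterial).
#'
#' @return An object of class `filter_params` (a validated list).
#' @export
#' @examples
#' filter_params()
#' filter_params(A_hat = 0, B_hat = c(0.7, 1.3))
filter_params <- function(A_hat = 0.8, B_hat = 0.6, H = 1, R = 0.8^2,
                          Q0 = 0.4^2, Qu = 0.4^2, P0 = 1e6, x0 = 0) {
  stopifnot(is.numeric(A_hat), length(A_hat) == 1,
            is.numeric(B_hat), length(B_hat) >= 0,
            is.numeric(H), length(H) == 1)
  if (A_hat < 0) abort("`A_hat` must be >= 0 (negative persistence is not supported).")
  if (!is.numeric(R) || length(R) != 1 || R <= 0) abort("`R` must be a single positive variance.")
  if (Q0 < 0) abort("`Q0` must be >= 0.")
  if (Qu < 0) abort("`Qu` must be >= 0.")
  if (P0 <= 0) abort("`P0` must be > 0.")
  structure(
    list(A_hat = A_hat, B_hat = as.numeric(B_hat), H = H, R = R,
         Q0 = Q0, Qu = Qu, P0 = P0, x0 = x0, m = length(B_hat)),
    class = "filter_params"
  )
}

#' @export
print.filter_params <- function(x, ...) {
  cat("<filter_params>  single-layer perception filter\n")
  cat(sprintf("  A_hat = %g, B_hat = [%s]  (m = %d)\n",
              x$A_hat, paste(signif(x$B_hat, 6), collapse = ", "), x$m))
  cat(sprintf("  H = %g, R = %g, Q0 = %g, Qu = %g, P0 = %g, x0 = %g\n",
              x$H, x$R, x$Q0, x$Qu, x$P0, x$x0))
  invisible(x)
}

#' Hierarchical-filter parameters
#'
#' Extends [filter_params()] with the second, parameter-estimation Kalman
#' filter that adapts the internal model `p = c(A_hat, B_hat)` from the
#' prediction error between perceived and expected pain. In hierarchical
#' mode the baseline process noise defaults to `Q0 = 0.1^2` (smaller than
#' the single-layer `0.4^2`) because the parameter-uncertainty term
#' `Hp %*% P_p %*% t(Hp)` now accounts explicitly for part of the prior
#' variance.
#'
#' @inheritParams filter_params
#' @param Q_p Diagonal of the internal-model noise covariance, either a
#'   single value recycled to length `1 + m` or a vector
#'   `c(Q_A, Q_b1, ..., Q_bm)`. Default `0.002^2` per entry.
#' @param P_p0 Initial parameter covariance: a single value (times identity)
#'   or a full `(1+m) x (1+m)` matrix. Default `1e6`.
#' @param legacy_pp_update Use the unscaled covariance update
#'   `P_p = Pbar_p (I - K_p Hp)` instead of the gain-scaled
#'   `P_p = Pbar_p (I - K * K_p Hp)`. The scaled form is the model default:
#'   it keeps the parameter covariance from collapsing to zero when sensory
#'   noise is infinite (no information should not mean high confidence).
#'   The legacy form is provided for comparison only.
#'
#' @return An object of class `hier_params` (inherits `filter_params`).
#' @export
#' @examples
#' hier_params()
#' hier_params(B_hat = c(0.9, 0.9), Q_p = c(0, 0.002^2, 0.002^2))
hier_params <- function(A_hat = 0.8, B_hat = 0.6, H = 1, R = 0.8^2,
                        Q0 = 0.1^2, Qu = 0.4^2, P0 = 1e6, x0 = 0,
                        Q_p = 0.002^2, P_p0 = 1e6,
                        legacy_pp_update = FALSE) {
  base <- filter_params(A_hat = A_hat, B_hat = B_hat, H = H, R = R,
                        Q0 = Q0, Qu = Qu, P0 = P0, x0 = x0)
  d <- 1L + base$m
  if (length(Q_p) == 1) Q_p <- rep(Q_p, d)
  if (length(Q_p) != d) abort(sprintf("`Q_p` must have length 1 or %d.", d))
  if (any(Q_p < 0)) abort("`Q_p` entries must be >= 0.")
  if (is.matrix(P_p0)) {
    if (!all(dim(P_p0) == d)) abort(sprintf("`P_p0` matrix must be %d x %d.", d, d))
  } else {
    if (length(P_p0) != 1 || P_p0 < 0) abort("`P_p0` must be a non-negative scalar or a matrix.")
    P_p0 <- diag(P_p0, d)
  }
  out <- c(base, list(Q_p = as.numeric(Q_p), P_p0 = P_p0,
                      legacy_pp_update = isTRUE(legacy_pp_update)))
  class(out) <- c("hier_params", "filter_params")
  out
}

#' @export
print.hier_params <- function(x, ...) {
  cat("<hier_params>  hierarchical perception filter\n")
  cat(sprintf("  p0 = [%s]  (A_hat, then %d control gains)\n",
              paste(signif(c(x$A_hat, x$B_hat), 6), collapse = ", "), x$m))
  cat(sprintf("  H = %g, R = %g, Q0 = %g, Qu = %g, P0 = %g, x0 = %g\n",
              x$H, x$R, x$Q0, x$Qu, x$P0, x$x0))
  cat(sprintf("  diag(Q_p) = [%s], P_p0[1,1] = %g, legacy_pp_update = %s\n",
              paste(signif(x$Q_p, 6), collapse = ", "),
              x$P_p0[1, 1], x$legacy_pp_update))
  invisible(x)
}

#' True-world parameters
#'
#' The "real" tissue-damage process that the perception filter observes:
#' `x(k) = A * x(k-1) + B * u_tilde(k)`, clipped defensively to the pain
#' scale bounds, with sensory input drawn from `N(H * x, R)` truncated to
#' the bounds by resampling.
#'
#' @param A True tissue-recovery/persistence coefficient.
#' @param B True gain from the damage input `u_tilde` (default 0.8).
#' @param H Observation mapping (default 1).
#' @param bounds Sensory truncation bounds, default `c(0, 10)` (the 11-point
#'   pain scale).
#'
#' @return An object of class `world_params`.
#' @export
#' @examples
#' world_params(A = 0.9)
world_params <- function(A = 0.9, B = 0.8, H = 1, bounds = c(0, 10)) {
  stopifnot(is.numeric(A), length(A) == 1, is.numeric(B), length(B) == 1,
            is.numeric(bounds), length(bounds) == 2)
  if (bounds[1] >= bounds[2]) abort("`bounds[1]` must be < `bounds[2]`.")
  structure(list(A = A, B = B, H = H, bounds = as.numeric(bounds)),
            class = "world_params")
}

#' @export
print.world_params <- function(x, ...) {
  cat(sprintf("<world_params>  x(k) = %g x(k-1) + %g u~(k), z ~ N(%g x, R) on [%g, %g]\n",
              x$A, x$B, x$H, x$bounds[1], x$bounds[2]))
  invisible(x)
}
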