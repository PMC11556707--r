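#' Build a stimulus schedule
#'
#' A stimulus schedule is a tibble with one row per time step holding the
#' world inputs: the tissue-damage input `u_tilde`, the cue/control input
#' columns `u1 ... um`, and the (possibly time-varying) sensory-noise
#' variance `R`. A step change in `R` models a nerve injury; its index can
#' be recorded for annotation.
#'
#' @param n_steps Number of time steps.
#' @param u_tilde Damage input per step (scalar recycled, or length
#'   `n_steps`).
#' @param u Control/cue input: a scalar or vector (one channel), or an
#'   `n_steps x m` matrix.
#' @param R Sensory-noise variance per step (scalar recycled or length
#'   `n_steps`); all entries must be positive.
#' @param injury_step Optional index at which `R` changes (annotation only).
#' @return A tibble of class `stimulus_schedule` with columns `step`,
#'   `u_tilde`, `u1..um`, `R`, and attributes `m` and `injury_step`.
#' @export
#' @examples
#' # an impulse at step 20, cued:
#' sch <- stimulus_schedule(100, u_tilde = impulse_at(100, 20), u = impulse_at(100, 20))
stimulus_schedule <- function(n_steps, u_tilde = 0, u = 0, R = 0.8^2,
                              injury_step = NULL) {
  stopifnot(n_steps >= 1)
  u_tilde <- rep_len(u_tilde, n_steps)
  if (!is.matrix(u)) u <- matrix(rep_len(u, n_steps), ncol = 1)
  if (nrow(u) != n_steps) abort("`u` must have `n_steps` rows.")
  R <- rep_len(R, n_steps)
  if (any(R <= 0)) abort("all `R` entries must be > 0.")
  m <- ncol(u)
  out <- tibble::tibble(step = seq_len(n_steps), u_tilde = u_tilde)
  for (j in seq_len(m)) out[[paste0("u", j)]] <- u[, j]
  out$R <- R
  attr(out, "m") <- m
  attr(out, "injury_step") <- injury_step
  class(out) <- c("stimulus_schedule", class(out))
  out
}

#' Impulse input vector
#'
#' A length-`n_steps` vector equal to `value` at the steps in `at` and 0
#' elsewhere; the standard stimulus shape of the simulations (an impulse of
#' magnitude 3.7).
#'
#' @param n_steps Length of the vector.
#' @param at Step indices of the impulses.
#' @param value Impulse magnitude (default 3.7).
#' @return Numeric vector.
#' @export
impulse_at <- function(n_steps, at, value = 3.7) {
  v <- numeric(n_steps)
  v[at[at >= 1 & at <= n_steps]] <- value
  v
}

# Extract the control-input matrix (n x m) from a schedule tibble.
schedule_u <- function(schedule) {
  m <- attr(schedule, "m") %||% length(grep("^u[0-9]+$", names(schedule)))
  as.matrix(schedule[paste0("u", seq_len(m))])
}
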