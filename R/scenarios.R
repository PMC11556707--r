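# Scenario engines: each run_* function reproduces one simulation protocol
# (conditioned placebo/nocebo, chronic pain, neuropathic-pain sweeps,
# pain-history risk factors, offset analgesia) from synthetic inputs only,
# and aggregates replicates into the reporting convention of the model
# (median/IQR over runs, mean/SE over simulated individuals).

new_scenario_result <- function(name, model, config, ...) {
  structure(
    c(list(name = name, model = model, config = config), list(...)),
    class = "painkf_scenario"
  )
}

# Stack replicate trajectories of one schedule into a long tibble.
run_replicates <- function(schedule, params, model = c("single", "hierarchical"),
                           n_replicates = 100, seed = 1,
                           world = world_params(), x_true = NULL,
                           P_init = NULL,
                           sample_process_noise = TRUE,
                           sample_param_noise = TRUE) {
  model <- match.arg(model)
  purrr::map_dfr(seq_len(n_replicates), function(i) {
    tr <- if (model == "single") {
      run_filter(schedule, params, world = world, seed = seed, replicate = i,
                 sample_process_noise = sample_process_noise, x_true = x_true)
    } else {
      run_hier_filter(schedule, params, world = world, seed = seed,
                      replicate = i,
                      sample_process_noise = sample_process_noise,
                      sample_param_noise = sample_param_noise,
                      x_true = x_true, P_init = P_init)
    }
    tr$replicate <- i
    tr
  })
}

# Balanced, per-individual-shuffled cue x heat test design: `per_cell`
# trials in each of the 4 cells, order shuffled under the individual's
# stream so pairings are independent of the learning history.
test_design <- function(per_cell = 10) {
  d <- tidyr::expand_grid(cue = c("placebo", "nocebo"),
                          heat = c("low", "high"))
  d <- d[rep(seq_len(nrow(d)), each = per_cell), ]
  d[sample.int(nrow(d)), ]
}

cue_u <- function(cue, u_mag) {
  cbind(u1 = ifelse(cue == "placebo", u_mag, 0),
        u2 = ifelse(cue == "nocebo", u_mag, 0))
}

# The placebo/nocebo label permutation: exchange the cue names (and the
# per-cue gain columns) while leaving all numeric trial quantities
# untouched. Under this permutation the output cells must swap exactly.
swap_cue_column <- function(trials) {
  trials$cue <- ifelse(trials$cue == "placebo", "nocebo", "placebo")
  bp <- trials$b_placebo
  trials$b_placebo <- trials$b_nocebo
  trials$b_nocebo <- bp
  trials
}

#' Placebo and nocebo with the single-layer filter
#'
#' Simulates test trials as discrete events (`A_hat = 0`): on each trial a
#' cue (placebo or nocebo, orthogonal control-input vectors of identical
#' magnitude `u_mag`) precedes a noxious heat stimulus whose tissue-damage
#' level is `x_low` (47 degree trials) or `x_high` (48 degree trials),
#' independent of the cue. Placebo/nocebo arises purely from the cue gains:
#' per individual, `b_placebo ~ N(0.7, 0.5^2)` and `b_nocebo ~ N(1.3,
#' 0.5^2)`, truncated at 0. The expected pain is the prior
#' `b_cue * u_mag`; the perceived pain fuses it with the truncated-Gaussian
#' sensory input.
#'
#' @param n_individuals Number of simulated individuals (default 28).
#' @param trials_per_cell Test trials per cue x heat cell (default 10, i.e.
#'   40 trials).
#' @param u_mag Cue magnitude (default 3.7).
#' @param b_mean Named means of the cue-gain distributions
#'   (`c(placebo = 0.7, nocebo = 1.3)`).
#' @param b_sd Inter-individual SD of the cue gains (default 0.5; set 0 for
#'   the deterministic prior check).
#' @param x_levels Tissue damage by heat level (`c(low = 3.1, high = 4.3)`).
#' @param R Sensory-noise variance (default `0.8^2`).
#' @param params Baseline [filter_params()]; `A_hat` is forced to 0 and
#'   `B_hat` replaced by the individual draws.
#' @param seed Base seed.
#' @param sample_process_noise Sample process noise into the prior mean.
#' @param swap_cue_labels Apply the placebo/nocebo label permutation: the
#'   cue names are exchanged while every numeric quantity (channel, gain
#'   draw, heat, sensory input) is untouched, so the placebo label now
#'   carries the `N(1.3, 0.5^2)` law and the output cells swap exactly
#'   (label-symmetry checks).
#' @return A `painkf_scenario` with `$trials` (per-individual trial log)
#'   and `$cells` (mean and SE of expected and perceived pain per cue x
#'   heat cell).
#' @export
#' @examples
#' res <- run_placebo_nocebo_single(n_individuals = 4, seed = 1)
#' tidy(res)
run_placebo_nocebo_single <- function(n_individuals = 28,
                                      trials_per_cell = 10,
                                      u_mag = 3.7,
                                      b_mean = c(placebo = 0.7, nocebo = 1.3),
                                      b_sd = 0.5,
                                      x_levels = c(low = 3.1, high = 4.3),
                                      R = 0.8^2,
                                      params = filter_params(),
                                      seed = 1,
                                      sample_process_noise = TRUE,
                                      swap_cue_labels = FALSE) {
  trials <- purrr::map_dfr(seq_len(n_individuals), function(i) {
    ind <- with_stream_seed(stream_seed(seed, i, "individual"), {
      b <- rtrunc_lower(2, b_mean, b_sd, lower = 0)
      list(b = b, design = test_design(trials_per_cell))
    })
    des <- ind$design
    n <- nrow(des)
    x <- unname(x_levels[des$heat])
    z <- with_stream_seed(stream_seed(seed, i, "sensory"),
                          sample_sensory(x, R = R))
    w <- if (sample_process_noise) {
      with_stream_seed(stream_seed(seed, i, "process"), rnorm(n))
    }
    p <- filter_params(A_hat = 0, B_hat = ind$b, H = params$H, R = R,
                       Q0 = params$Q0, Qu = params$Qu, P0 = params$P0)
    tr <- kf_core(p, cue_u(des$cue, u_mag), rep(R, n), z, w = w, x_true = x)
    tibble::tibble(individual = i, trial = seq_len(n),
                   cue = des$cue, heat = des$heat, x = x, z = z,
                   b_placebo = ind$b[1], b_nocebo = ind$b[2],
                   expected = tr$xbar_hat, perceived = tr$x_hat)
  })
  if (swap_cue_labels) trials <- swap_cue_column(trials)
  ind_cells <- trials |>
    tidyr::pivot_longer(c("expected", "perceived"), names_to = "measure") |>
    dplyr::group_by(.data$individual, .data$cue, .data$heat, .data$measure) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  cells <- aggregate_runs(ind_cells, "individual", value = "value",
                          by = c("cue", "heat", "measure"))
  new_scenario_result(
    "placebo_nocebo_single", "single",
    list(n_individuals = n_individuals, trials_per_cell = trials_per_cell,
         u_mag = u_mag, b_mean = b_mean, b_sd = b_sd, x_levels = x_levels,
         R = R, seed = seed, sample_process_noise = sample_process_noise,
         swap_cue_labels = swap_cue_labels),
    trials = trials, cells = cells
  )
}

#' Classical conditioning with the hierarchical filter
#'
#' Conditioning phase: over `n_conditioning` trials the placebo cue is
#' paired with low heat (sensory input `z ~ N(z_means["low"], R)`) and the
#' nocebo cue with high heat (`z ~ N(z_means["high"], R)`), both truncated
#' to the pain scale. The cue gains start from a common law
#' `N(b0_mean, b0_sd^2)` truncated at 0 and differentiate through the
#' parameter filter. Test phase: as in [run_placebo_nocebo_single()], cue
#' and heat fully crossed. Trials are discrete events, so the persistence
#' parameter is frozen at `A_hat = 0` (its noise and covariance entries
#' zeroed) and only the cue gains learn.
#'
#' @inheritParams run_placebo_nocebo_single
#' @param n_conditioning Number of conditioning trials (default 120).
#' @param b0_mean,b0_sd Initial cue-gain law (defaults 0.9 and 0.8).
#' @param z_means Conditioning sensory-input means
#'   (`c(low = 2.2, high = 5.2)`).
#' @param Q_b Internal-model noise variance per cue gain (default
#'   `0.002^2`).
#' @param P_p0_b Initial parameter variance per cue gain. Default
#'   `b0_sd^2`: the belief uncertainty that is consistent with the gains
#'   actually being drawn from the `N(b0_mean, b0_sd^2)` prior. (A very
#'   large initial covariance is not usable here: the prediction error's
#'   true sensitivity to a gain error is `-K u` while the parameter filter
#'   observes through `(1 - K) u`, so on cue trials — where the
#'   control-dependent process noise makes `K` about 0.78 — an
#'   uncertainty-dominated gain over-corrects by a factor `K/(1-K) > 2`
#'   and the gains diverge.)
#' @param Q0 Baseline process-noise variance (hierarchical default
#'   `0.1^2`).
#' @param Qu Control-dependent process-noise coefficient (default `0.4^2`).
#' @param freeze_gains Zero `Q_b` and `P_p0_b` so no learning occurs (the
#'   frozen-parameter control).
#' @return A `painkf_scenario` with `$b_trajectories` (median/IQR of both
#'   gains per conditioning trial), `$conditioning` (per-trial expected
#'   pain by cue), `$cells` (test-phase mean/SE), and `$trials`.
#' @export
#' @examples
#' res <- run_conditioning_hier(n_individuals = 4, n_conditioning = 30, seed = 1)
#' glance(res)
run_conditioning_hier <- function(n_individuals = 28,
                                  n_conditioning = 120,
                                  trials_per_cell = 10,
                                  u_mag = 3.7,
                                  b0_mean = 0.9, b0_sd = 0.8,
                                  z_means = c(low = 2.2, high = 5.2),
                                  x_levels = c(low = 3.1, high = 4.3),
                                  R = 0.8^2,
                                  Q_b = 0.002^2, P_p0_b = NULL,
                                  Q0 = 0.1^2, Qu = 0.4^2,
                                  seed = 1,
                                  sample_process_noise = TRUE,
                                  sample_param_noise = TRUE,
                                  freeze_gains = FALSE,
                                  swap_cue_labels = FALSE) {
  P_p0_b <- P_p0_b %||% b0_sd^2
  if (freeze_gains) {
    Q_b <- 0
    P_p0_b <- 0
  }
  trials <- purrr::map_dfr(seq_len(n_individuals), function(i) {
    ind <- with_stream_seed(stream_seed(seed, i, "individual"), {
      b0 <- rtrunc_lower(2, b0_mean, b0_sd, lower = 0)
      cond_cue <- sample(rep(c("placebo", "nocebo"), length.out = n_conditioning))
      list(b0 = b0, cond_cue = cond_cue, design = test_design(trials_per_cell))
    })
    cond_heat <- ifelse(ind$cond_cue == "placebo", "low", "high")
    des <- ind$design
    cue <- c(ind$cond_cue, des$cue)
    heat <- c(cond_heat, des$heat)
    phase <- rep(c("conditioning", "test"),
                 c(n_conditioning, nrow(des)))
    mu <- ifelse(phase == "conditioning",
                 unname(z_means[heat]), unname(x_levels[heat]))
    n <- length(mu)
    z <- with_stream_seed(stream_seed(seed, i, "sensory"),
                          sample_sensory(mu, R = R))
    p <- hier_params(A_hat = 0, B_hat = ind$b0, R = R, Q0 = Q0, Qu = Qu,
                     Q_p = c(0, Q_b, Q_b),
                     P_p0 = diag(c(0, P_p0_b, P_p0_b)))
    ns <- draw_noise_streams(seed, i, n, 3L)
    tr <- hkf_core(p, cue_u(cue, u_mag), rep(R, n), z,
                   w = if (sample_process_noise) ns$process,
                   wp = if (sample_param_noise) ns$param,
                   x_true = mu)
    tibble::tibble(individual = i, trial = seq_len(n), phase = phase,
                   cue = cue, heat = heat, x = mu, z = z,
                   expected = tr$xbar_hat, perceived = tr$x_hat,
                   b_placebo = tr$b1, b_nocebo = tr$b2)
  })
  if (swap_cue_labels) trials <- swap_cue_column(trials)
  cond <- dplyr::filter(trials, .data$phase == "conditioning")
  b_traj <- cond |>
    tidyr::pivot_longer(c("b_placebo", "b_nocebo"), names_to = "gain",
                        names_prefix = "b_") |>
    aggregate_runs("replicate", value = "value", by = c("trial", "gain"))
  conditioning <- aggregate_runs(cond, "individual", value = "expected",
                                 by = c("trial", "cue"))
  test <- dplyr::filter(trials, .data$phase == "test")
  ind_cells <- test |>
    tidyr::pivot_longer(c("expected", "perceived"), names_to = "measure") |>
    dplyr::group_by(.data$individual, .data$cue, .data$heat, .data$measure) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  cells <- aggregate_runs(ind_cells, "individual", value = "value",
                          by = c("cue", "heat", "measure"))
  new_scenario_result(
    "conditioning_hier", "hierarchical",
    list(n_individuals = n_individuals, n_conditioning = n_conditioning,
         trials_per_cell = trials_per_cell, u_mag = u_mag,
         b0_mean = b0_mean, b0_sd = b0_sd, z_means = z_means,
         x_levels = x_levels, R = R, Q_b = Q_b, P_p0_b = P_p0_b,
         seed = seed, freeze_gains = freeze_gains,
         swap_cue_labels = swap_cue_labels),
    trials = trials, b_trajectories = b_traj, conditioning = conditioning,
    cells = cells
  )
}

#' Chronic pain after a transient injury
#'
#' A cued tissue-damage impulse (`u_tilde = u = 3.7` at `impulse_step`)
#' drives the world `x(k) = A x(k-1) + B u_tilde(k)`; the filter believes
#' `A_hat = 1` (pain expected to persist). With low sensory noise the
#' perceived pain tracks the recovering damage; with elevated noise the
#' persistent prior dominates and pain outlasts the damage.
#'
#' @param R_values Sensory-noise variances to contrast (default
#'   `c(0.8^2, 1.8^2)`).
#' @param n_steps Steps per run (default 150).
#' @param impulse_step Step of the damage impulse (default 20).
#' @param n_replicates Simulation runs per condition (default 100).
#' @param A_hat Believed persistence (default 1).
#' @param world True-world parameters (default `A = 0.9`, `B = 0.8`).
#' @param cued Pair the damage input with an identical control input
#'   (`TRUE`, seeing the hammer approach) or leave the filter uncued
#'   (`FALSE`, the unnoticed bee sting).
#' @param params Baseline [filter_params()] for the remaining constants.
#' @param seed Base seed.
#' @param sample_process_noise Sample process noise into the prior mean.
#' @return A `painkf_scenario` with `$trajectories` (per-step median/IQR of
#'   perceived pain per `R`), `$summary` (post-recovery medians), and
#'   `$runs`.
#' @export
#' @examples
#' res <- run_chronic_pain(n_replicates = 5, n_steps = 60, seed = 1)
#' tidy(res)
run_chronic_pain <- function(R_values = c(0.8^2, 1.8^2),
                             n_steps = 150, impulse_step = 20,
                             n_replicates = 100, A_hat = 1,
                             world = world_params(A = 0.9, B = 0.8),
                             cued = TRUE,
                             params = filter_params(),
                             seed = 1, sample_process_noise = TRUE) {
  runs <- purrr::map_dfr(R_values, function(Rv) {
    imp <- impulse_at(n_steps, impulse_step)
    sch <- stimulus_schedule(n_steps, u_tilde = imp,
                             u = if (cued) imp else 0, R = Rv)
    p <- filter_params(A_hat = A_hat, B_hat = params$B_hat, H = params$H,
                       R = Rv, Q0 = params$Q0, Qu = params$Qu,
                       P0 = params$P0)
    out <- run_replicates(sch, p, "single", n_replicates, seed,
                          world = world,
                          sample_process_noise = sample_process_noise)
    out$R_condition <- Rv
    out
  })
  traj <- runs |>
    aggregate_runs("replicate", value = "x_hat",
                   by = c("R_condition", "step")) |>
    dplyr::left_join(dplyr::distinct(runs, .data$R_condition, .data$step,
                                     .data$x),
                     by = c("R_condition", "step"))
  post <- dplyr::filter(runs, .data$step > impulse_step, .data$x < 0.1)
  summary <- post |>
    dplyr::group_by(.data$replicate, .data$R_condition) |>
    dplyr::summarise(x_hat = median(.data$x_hat), .groups = "drop") |>
    dplyr::group_by(.data$R_condition) |>
    dplyr::summarise(post_recovery_median_xhat = median(.data$x_hat),
                     .groups = "drop")
  new_scenario_result(
    "chronic_pain", "single",
    list(R_values = R_values, n_steps = n_steps,
         impulse_step = impulse_step, n_replicates = n_replicates,
         A_hat = A_hat, cued = cued, seed = seed),
    runs = runs, trajectories = traj, summary = summary
  )
}

#' Uncued injury (damage without a predictive cue)
#'
#' The bee-sting variant of [run_chronic_pain()]: the damage input arrives
#' with no control input (`u = 0` throughout), so the prior cannot
#' anticipate the damage and the perceived pain rises only once the sensory
#' input reports it.
#'
#' @inheritParams run_chronic_pain
#' @param R Sensory-noise variance (default `0.8^2`).
#' @return A `painkf_scenario`, as [run_chronic_pain()].
#' @export
run_uncued_injury <- function(R = 0.8^2, n_steps = 150, impulse_step = 20,
                              n_replicates = 100, A_hat = 0.8,
                              world = world_params(A = 0.9, B = 0.8),
                              params = filter_params(),
                              seed = 1, sample_process_noise = TRUE) {
  res <- run_chronic_pain(R_values = R, n_steps = n_steps,
                          impulse_step = impulse_step,
                          n_replicates = n_replicates, A_hat = A_hat,
                          world = world, cued = FALSE, params = params,
                          seed = seed,
                          sample_process_noise = sample_process_noise)
  res$name <- "uncued_injury"
  res$config$cued <- FALSE
  res
}

#' Neuropathic-pain sweep, single-layer filter
#'
#' After a baseline period at low sensory noise (letting the posterior
#' variance settle to its steady state), the sensory-noise variance jumps
#' to `R` (the nerve injury) while the true damage stays at zero. The
#' resulting spontaneous pain depends on the believed persistence `A_hat`
#' and on `R`: with `A_hat > 1` and large `R` the prior predicts growing
#' pain and dominates the noisy input.
#'
#' @param A_hat_values Persistence grid (default `c(0.9, 1.0, 1.1)`).
#' @param R_values Post-injury noise grid (default
#'   `c(0.8^2, 80^2, 800^2)`).
#' @param baseline_steps Baseline steps at `R = 0.8^2` (default 200).
#' @param post_steps Post-injury steps (default 300).
#' @inheritParams run_chronic_pain
#' @return A `painkf_scenario` with `$trajectories` (median/IQR per
#'   `A_hat` x `R` cell) and `$runs`.
#' @export
run_neuropathic_single_sweep <- function(A_hat_values = c(0.9, 1.0, 1.1),
                                         R_values = c(0.8^2, 80^2, 800^2),
                                         baseline_steps = 200,
                                         post_steps = 300,
                                         n_replicates = 100,
                                         params = filter_params(),
                                         seed = 1,
                                         sample_process_noise = TRUE) {
  grid <- tidyr::expand_grid(A_hat = A_hat_values, R_post = R_values)
  runs <- purrr::pmap_dfr(grid, function(A_hat, R_post) {
    n <- baseline_steps + post_steps
    sch <- stimulus_schedule(
      n, u_tilde = 0, u = 0,
      R = rep(c(params$R, R_post), c(baseline_steps, post_steps)),
      injury_step = baseline_steps + 1L
    )
    p <- filter_params(A_hat = A_hat, B_hat = params$B_hat, H = params$H,
                       R = params$R, Q0 = params$Q0, Qu = params$Qu,
                       P0 = params$P0)
    out <- run_replicates(sch, p, "single", n_replicates, seed,
                          sample_process_noise = sample_process_noise)
    out$A_hat_cell <- A_hat
    out$R_cell <- R_post
    out
  })
  traj <- aggregate_runs(runs, "replicate", value = "x_hat",
                         by = c("A_hat_cell", "R_cell", "step"))
  new_scenario_result(
    "neuropathic_single_sweep", "single",
    list(A_hat_values = A_hat_values, R_values = R_values,
         baseline_steps = baseline_steps, post_steps = post_steps,
         n_replicates = n_replicates, seed = seed),
    runs = runs, trajectories = traj
  )
}

#' Neuropathic-pain sweep, hierarchical filter
#'
#' Post-injury runs starting from a converged baseline belief (`P = 1`,
#' `P_p = I` at the moment of nerve injury; the posterior mean starts at
#' 0), for a grid of initial persistence beliefs `A_hat0` and sensory-noise
#' levels `R`. With very large `R` the parameter filter receives no
#' information and the believed persistence reduces to a random walk
#' centred at its initial value with the internal-model noise variance.
#'
#' @param A0_values Initial persistence grid (default `c(0.9, 1.0, 1.1)`).
#' @param R_values Noise grid (default `c(0.8^2, 8^2, 80^2, 800^2)`).
#' @param n_steps Post-injury steps (default 1000).
#' @param n_replicates Simulation runs per cell (default 100).
#' @param params Baseline [hier_params()].
#' @param seed Base seed.
#' @param sample_process_noise,sample_param_noise Noise-sampling flags.
#' @return A `painkf_scenario` with `$trajectories` (median/IQR of both
#'   `x_hat` and `A_hat` per cell) and `$runs`.
#' @export
run_neuropathic_hier_sweep <- function(A0_values = c(0.9, 1.0, 1.1),
                                       R_values = c(0.8^2, 8^2, 80^2, 800^2),
                                       n_steps = 1000,
                                       n_replicates = 100,
                                       params = hier_params(),
                                       seed = 1,
                                       sample_process_noise = TRUE,
                                       sample_param_noise = TRUE) {
  grid <- tidyr::expand_grid(A0 = A0_values, R_post = R_values)
  runs <- purrr::pmap_dfr(grid, function(A0, R_post) {
    sch <- stimulus_schedule(n_steps, u_tilde = 0, u = 0, R = R_post,
                             injury_step = 1L)
    p <- hier_params(A_hat = A0, B_hat = params$B_hat, R = R_post,
                     Q0 = params$Q0, Qu = params$Qu, P0 = params$P0,
                     Q_p = params$Q_p, P_p0 = diag(1, 1 + params$m),
                     legacy_pp_update = params$legacy_pp_update)
    out <- run_replicates(sch, p, "hierarchical", n_replicates, seed,
                          P_init = 1,
                          sample_process_noise = sample_process_noise,
                          sample_param_noise = sample_param_noise)
    out$A0_cell <- A0
    out$R_cell <- R_post
    out
  })
  traj <- dplyr::bind_rows(
    x_hat = aggregate_runs(runs, "replicate", value = "x_hat",
                           by = c("A0_cell", "R_cell", "step")),
    A_hat = aggregate_runs(runs, "replicate", value = "A_hat",
                           by = c("A0_cell", "R_cell", "step")),
    .id = "variable"
  )
  new_scenario_result(
    "neuropathic_hier_sweep", "hierarchical",
    list(A0_values = A0_values, R_values = R_values, n_steps = n_steps,
         n_replicates = n_replicates, seed = seed),
    runs = runs, trajectories = traj
  )
}

#' Pain history as a risk factor for neuropathic pain
#'
#' Three pre-injury histories shape the learned persistence: slowly
#' recovering damage (`A = 0.99`) with periodic noxious impulses, quickly
#' recovering damage (`A = 0.9`) with the same impulses, and no stimuli at
#' all. A nerve injury (step change of `R` to `800^2`) follows; the learned
#' `A_hat` at injury determines the subsequent spontaneous pain. Without
#' decay episodes to learn from (no-stimuli history) the belief settles
#' near `A_hat = 1` and the post-injury risk is elevated.
#'
#' The run starts from a converged parameter belief (`P_p0 = I`): an
#' uncertainty-dominated parameter filter over-corrects on cue trials
#' (where the control-dependent process noise pushes the state gain above
#' 2/3) and the persistence estimate diverges, so the enormous
#' uninformed-prior covariance is not a usable starting point for a
#' stimulated history.
#'
#' @param histories A tibble with columns `history`, `A`, `stimuli`
#'   (logical); defaults to the three histories above.
#' @param pre_steps Pre-injury steps (default 600).
#' @param post_steps Post-injury steps (default 200; the summary window
#'   must overlap the horizon on which the learned beliefs still differ —
#'   the post-injury pain-decay time constant is about
#'   `1 / (1 - A_hat)` steps, so far longer horizons leave every history
#'   at the sensory floor).
#' @param impulse_every Impulse period during the history (default 50).
#' @param R_injury Post-injury sensory-noise variance (default `800^2`).
#' @param window_frac Fraction of the post-injury period (from the end)
#'   summarised as the post-injury pain level (default 0.25).
#' @param world_B True damage gain (default 0.8).
#' @inheritParams run_neuropathic_hier_sweep
#' @return A `painkf_scenario` with `$trajectories`, `$summary` (per
#'   history: terminal pre-injury `A_hat` and post-injury window median
#'   `x_hat`, medians over replicates) and `$runs`.
#' @export
run_history_risk <- function(histories = NULL,
                             pre_steps = 600, post_steps = 200,
                             impulse_every = 50, R_injury = 800^2,
                             window_frac = 0.25, world_B = 0.8,
                             n_replicates = 100,
                             params = hier_params(P_p0 = 1),
                             seed = 1,
                             sample_process_noise = TRUE,
                             sample_param_noise = TRUE) {
  if (is.null(histories)) {
    histories <- tibble::tibble(
      history = c("persistent", "transient", "no_stimuli"),
      A = c(0.99, 0.9, 0.9),
      stimuli = c(TRUE, TRUE, FALSE)
    )
  }
  n <- pre_steps + post_steps
  runs <- purrr::pmap_dfr(histories, function(history, A, stimuli) {
    at <- if (stimuli) seq(impulse_every, pre_steps - impulse_every,
                           by = impulse_every)
    imp <- impulse_at(n, at %||% integer(0))
    sch <- stimulus_schedule(
      n, u_tilde = imp, u = imp,
      R = rep(c(params$R, R_injury), c(pre_steps, post_steps)),
      injury_step = pre_steps + 1L
    )
    out <- run_replicates(sch, params, "hierarchical", n_replicates, seed,
                          world = world_params(A = A, B = world_B),
                          sample_process_noise = sample_process_noise,
                          sample_param_noise = sample_param_noise)
    out$history <- history
    out
  })
  traj <- dplyr::bind_rows(
    x_hat = aggregate_runs(runs, "replicate", value = "x_hat",
                           by = c("history", "step")),
    A_hat = aggregate_runs(runs, "replicate", value = "A_hat",
                           by = c("history", "step")),
    .id = "variable"
  )
  window_start <- pre_steps + ceiling((1 - window_frac) * post_steps) + 1L
  summary <- runs |>
    dplyr::group_by(.data$history, .data$replicate) |>
    dplyr::summarise(
      terminal_A_hat = .data$A_hat[.data$step == pre_steps],
      post_injury_xhat = median(.data$x_hat[.data$step >= window_start]),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$history) |>
    dplyr::summarise(terminal_A_hat = median(.data$terminal_A_hat),
                     post_injury_xhat = median(.data$post_injury_xhat),
                     .groups = "drop")
  new_scenario_result(
    "history_risk", "hierarchical",
    list(histories = histories, pre_steps = pre_steps,
         post_steps = post_steps, impulse_every = impulse_every,
         R_injury = R_injury, window_frac = window_frac,
         n_replicates = n_replicates, seed = seed),
    runs = runs, trajectories = traj, summary = summary
  )
}

# Interval table for the offset-analgesia paradigm.
offset_intervals <- function(T1 = 49, T2 = 49, T3_block = 25, delta = 5) {
  starts <- cumsum(c(1, T1, T2, rep(T3_block, 3)))
  lens <- c(T1, T2, rep(T3_block, 4))
  tibble::tibble(
    interval = c("T1", "T2", "T3_1", "T3_2", "T3_3", "T3_4"),
    start = starts,
    end = starts + lens - 1,
    # omit the settling period after each temperature change
    assess_from = starts + c(delta, delta, delta, 0, 0, 0)
  )
}

#' Offset analgesia
#'
#' Noxious heat applied in three consecutive intervals: T1 and T3 at the
#' same temperature, T2 slightly higher; the control condition holds the T1
#' temperature throughout. Tissue damage is taken as linearly proportionate
#' to the applied temperature (an exact plateau profile), there are no
#' predictive cues (`u = 0`), and the internal model starts matched to the
#' world (`A_hat0 = A`) with converged belief uncertainty (`P = 1`,
#' `P_p = I`). Pain is assessed as the median perceived pain within
#' `T1, T2, T3_1..T3_4`, omitting the first `delta` steps after each
#' temperature change. The adaptive persistence belief produces an
#' underdamped response — a transient undershoot — after the T2 to T3
#' reduction.
#'
#' @param levels Damage levels `c(base, high)` for T1/T3 and T2 (default
#'   `c(3.1, 4.3)`, the 47/48 degree anchors).
#' @param T1,T2,T3_block Interval lengths in steps (defaults 49, 49, and
#'   4 blocks of 25).
#' @param delta Settling steps omitted after each temperature change
#'   (default 5).
#' @param A0 World recovery rate and matched initial persistence belief
#'   (default 0.9).
#' @param R Sensory-noise variance (default `0.8^2`).
#' @inheritParams run_neuropathic_hier_sweep
#' @return A `painkf_scenario` with `$interval_medians` (median/IQR across
#'   runs of the per-run interval medians, per condition), `$per_run`
#'   (per-run interval medians) and `$runs`.
#' @export
#' @examples
#' res <- run_offset_analgesia(n_replicates = 5, seed = 1)
#' tidy(res)
run_offset_analgesia <- function(levels = c(3.1, 4.3),
                                 T1 = 49, T2 = 49, T3_block = 25,
                                 delta = 5,
                                 A0 = 0.9, R = 0.8^2,
                                 n_replicates = 100,
                                 params = hier_params(),
                                 seed = 1,
                                 sample_process_noise = TRUE,
                                 sample_param_noise = TRUE) {
  iv <- offset_intervals(T1, T2, T3_block, delta)
  n <- max(iv$end)
  profile_offset <- rep(c(levels[1], levels[2], levels[1]),
                        c(T1, T2, 4 * T3_block))
  profile_control <- rep(levels[1], n)
  conds <- list(offset = profile_offset, control = profile_control)
  runs <- purrr::imap_dfr(conds, function(profile, cond) {
    sch <- stimulus_schedule(n, u_tilde = 0, u = 0, R = R)
    p <- hier_params(A_hat = A0, B_hat = params$B_hat, R = R,
                     Q0 = params$Q0, Qu = params$Qu, P0 = params$P0,
                     Q_p = params$Q_p, P_p0 = diag(1, 1 + params$m),
                     legacy_pp_update = params$legacy_pp_update)
    out <- run_replicates(sch, p, "hierarchical", n_replicates, seed,
                          x_true = profile, P_init = 1,
                          sample_process_noise = sample_process_noise,
                          sample_param_noise = sample_param_noise)
    out$condition <- cond
    out
  })
  per_run <- purrr::pmap_dfr(iv, function(interval, start, end, assess_from) {
    runs |>
      dplyr::filter(.data$step >= assess_from, .data$step <= end) |>
      dplyr::group_by(.data$condition, .data$replicate) |>
      dplyr::summarise(x_hat = median(.data$x_hat), .groups = "drop") |>
      dplyr::mutate(interval = interval)
  })
  per_run$interval <- factor(per_run$interval, levels = iv$interval)
  interval_medians <- aggregate_runs(per_run, "replicate", value = "x_hat",
                                     by = c("condition", "interval"))
  new_scenario_result(
    "offset_analgesia", "hierarchical",
    list(levels = levels, T1 = T1, T2 = T2, T3_block = T3_block,
         delta = delta, A0 = A0, R = R, n_replicates = n_replicates,
         seed = seed),
    runs = runs, per_run = per_run, interval_medians = interval_medians,
    intervals = iv
  )
}
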