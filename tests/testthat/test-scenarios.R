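test_that("replicate aggregation uses the interpolated-quantile convention", {
  tr <- tidyr::expand_grid(replicate = 1:5, step = 1:3)
  tr$x_hat <- tr$replicate
  agg <- aggregate_runs(tr, "replicate")
  expect_equal(agg$median, rep(3, 3))
  expect_equal(agg$q25, rep(2, 3))
  expect_equal(agg$q75, rep(4, 3))
  # degenerate spread
  tr$x_hat <- 1
  agg0 <- aggregate_runs(tr, "replicate")
  expect_true(all(agg0$q75 - agg0$q25 == 0))
  expect_error(aggregate_runs(tr[0, ], "replicate"), "no trajectories")
})

test_that("individual aggregation reports mean and inter-individual SE", {
  d <- tibble::tibble(individual = 1:28, cell = "a",
                      value = rnorm(28, 5, 2))
  agg <- aggregate_runs(d, "individual", value = "value", by = "cell")
  expect_equal(agg$mean, mean(d$value))
  expect_equal(agg$se, sd(d$value) / sqrt(28))
  expect_equal(agg$n, 28L)
})

test_that("cue-driven priors are exact when all noise is removed", {
  res <- run_placebo_nocebo_single(n_individuals = 4, b_sd = 0,
                                   sample_process_noise = FALSE, seed = 1)
  exp_cells <- dplyr::filter(tidy(res), measure == "expected")
  expect_equal(exp_cells$mean[exp_cells$cue == "placebo"],
               rep(0.7 * 3.7, 2))
  expect_equal(exp_cells$mean[exp_cells$cue == "nocebo"],
               rep(1.3 * 3.7, 2))
  expect_true(all(exp_cells$se == 0))
})

test_that("perceived pain tracks the stimulus exactly in the perfect-sensing limit", {
  res <- run_placebo_nocebo_single(n_individuals = 4, R = 1e-12, seed = 1)
  per <- dplyr::filter(tidy(res), measure == "perceived")
  expect_equal(per$mean[per$heat == "low"], rep(3.1, 2), tolerance = 1e-4)
  expect_equal(per$mean[per$heat == "high"], rep(4.3, 2), tolerance = 1e-4)
})

test_that("perceived pain increases with both temperature and cue", {
  res <- run_placebo_nocebo_single(n_individuals = 28, seed = 2)
  per <- dplyr::filter(tidy(res), measure == "perceived")
  g <- function(cue, heat) per$mean[per$cue == cue & per$heat == heat]
  expect_gt(g("nocebo", "high"), g("placebo", "high"))
  expect_gt(g("nocebo", "low"), g("placebo", "low"))
  expect_gt(g("placebo", "high"), g("placebo", "low"))
  expect_gt(g("nocebo", "high"), g("nocebo", "low"))
})

test_that("swapping cue labels swaps the output cells exactly", {
  a <- run_placebo_nocebo_single(n_individuals = 6, seed = 3)
  b <- run_placebo_nocebo_single(n_individuals = 6, seed = 3,
                                 swap_cue_labels = TRUE)
  ca <- dplyr::arrange(a$cells, cue, heat, measure)
  cb <- b$cells
  cb$cue <- ifelse(cb$cue == "placebo", "nocebo", "placebo")
  cb <- dplyr::arrange(cb, cue, heat, measure)
  expect_equal(ca, cb)
})

test_that("conditioning separates the cue gains in the learned direction", {
  res <- run_conditioning_hier(n_individuals = 28, seed = 4)
  bt <- res$b_trajectories
  first <- dplyr::filter(bt, trial == 1)
  last <- dplyr::filter(bt, trial == max(bt$trial))
  # baseline: the two gain distributions overlap (common initial law)
  expect_lt(abs(first$median[first$gain == "nocebo"] -
                  first$median[first$gain == "placebo"]), 0.4)
  expect_gt(last$median[last$gain == "nocebo"],
            last$median[last$gain == "placebo"])
  # test phase inherits the conditioned expectations
  per <- dplyr::filter(res$cells, measure == "perceived")
  g <- function(cue, heat) per$mean[per$cue == cue & per$heat == heat]
  expect_gt(g("nocebo", "high"), g("placebo", "high"))
  expect_gt(g("nocebo", "low"), g("placebo", "low"))
})

test_that("conditioning with identical pairings produces no separation beyond noise", {
  res <- run_conditioning_hier(n_individuals = 28, seed = 5,
                               z_means = c(low = 3.7, high = 3.7))
  last <- dplyr::filter(res$b_trajectories,
                        trial == max(res$b_trajectories$trial))
  sep <- last$median[last$gain == "nocebo"] -
    last$median[last$gain == "placebo"]
  expect_lt(abs(sep), 0.25)
})

test_that("frozen parameters are a flat-trajectory control", {
  res <- run_conditioning_hier(n_individuals = 6, seed = 6,
                               freeze_gains = TRUE,
                               sample_param_noise = FALSE)
  tr <- res$trials
  for (i in unique(tr$individual)) {
    bi <- tr$b_placebo[tr$individual == i]
    expect_equal(diff(range(bi)), 0)
  }
})

test_that("chronic pain persists only under elevated sensory noise", {
  res <- run_chronic_pain(n_replicates = 40, seed = 7)
  s <- res$summary
  expect_gt(s$post_recovery_median_xhat[s$R_condition == 1.8^2],
            s$post_recovery_median_xhat[s$R_condition == 0.8^2])
  # memoryless prior collapses onto the sensory input regardless of R
  res0 <- run_chronic_pain(n_replicates = 10, A_hat = 0, seed = 7)
  expect_lt(max(res0$summary$post_recovery_median_xhat), 1.0)
})

test_that("uncued damage elicits pain only after the sensory report", {
  res <- run_uncued_injury(n_replicates = 20, seed = 8)
  tr <- res$trajectories
  before <- dplyr::filter(tr, step < 20)
  after <- dplyr::filter(tr, step >= 21, step <= 25)
  expect_lt(max(before$median), 1)
  expect_gt(max(after$median), 1.5)
  # null world: perceived pain settles at the truncated-sensory floor
  # (E[z] ~ 0.64 for R = 0.8^2 around x = 0), well below any pain episode
  null <- run_chronic_pain(R_values = 0.64, n_replicates = 5, seed = 8,
                           n_steps = 50, impulse_step = 200)
  late <- dplyr::filter(null$trajectories, step > 10)
  expect_lt(median(abs(late$median)), 1)
})

test_that("single-layer neuropathic sweep reproduces the qualitative grid", {
  res <- run_neuropathic_single_sweep(
    A_hat_values = c(0.9, 1.1), R_values = c(0.8^2, 800^2),
    baseline_steps = 150, post_steps = 200, n_replicates = 30, seed = 9
  )
  tr <- res$trajectories
  tail_med <- function(A, R) {
    d <- dplyr::filter(tr, A_hat_cell == A, R_cell == R, step > 300)
    median(d$median)
  }
  expect_lt(tail_med(0.9, 0.8^2), 1)   # sensor-dominated, no pain
  expect_lt(tail_med(0.9, 800^2), 1.5) # decaying prior cannot sustain pain
  expect_gt(tail_med(1.1, 800^2), 5)   # growing prior saturates high
})

test_that("hierarchical sweep: moderate noise pulls the persistence belief to 1", {
  res <- run_neuropathic_hier_sweep(
    A0_values = c(0.9, 1.1), R_values = c(0.8^2, 8^2),
    n_steps = 600, n_replicates = 20, seed = 10
  )
  tr <- dplyr::filter(res$trajectories, variable == "A_hat", step == 600)
  for (a0 in c(0.9, 1.1)) {
    expect_lt(abs(tr$median[tr$A0_cell == a0 & tr$R_cell == 64] - 1), 0.05)
  }
  # low noise: pain stays near zero for either initial belief
  xh <- dplyr::filter(res$trajectories, variable == "x_hat",
                      R_cell == 0.8^2, step > 300)
  expect_lt(max(abs(xh$median)), 1)
  # frozen parameters: no walk without noise or initial uncertainty
  sch <- stimulus_schedule(100, R = 800^2)
  tr0 <- run_hier_filter(sch, hier_params(A_hat = 1, Q_p = 0, P_p0 = 0),
                         seed = 10, P_init = 1)
  expect_true(all(tr0$A_hat == 1.0))
})

test_that("pain history orders the learned persistence and post-injury risk", {
  res <- run_history_risk(n_replicates = 30, seed = 11)
  s <- res$summary
  g <- function(h, col) s[[col]][s$history == h]
  expect_gt(g("persistent", "terminal_A_hat"), g("transient", "terminal_A_hat"))
  expect_lt(abs(g("no_stimuli", "terminal_A_hat") - 1), 0.05)
  expect_gt(g("persistent", "post_injury_xhat"), g("transient", "post_injury_xhat"))
  expect_gte(g("no_stimuli", "post_injury_xhat"), g("transient", "post_injury_xhat"))
})

test_that("offset analgesia undershoots relative to the constant control", {
  res <- run_offset_analgesia(n_replicates = 40, seed = 12)
  m <- res$interval_medians
  g <- function(cond, iv) m$median[m$condition == cond & m$interval == iv]
  # control is flat across intervals
  ctrl <- vapply(levels(m$interval), function(iv) g("control", iv), 0)
  expect_lt(diff(range(ctrl)), 0.5)
  # undershoot in the first post-reduction interval
  expect_lt(g("offset", "T3_1"), g("control", "T3_1"))
  # null stimulus: flat zero
  # null stimulus: pain sits at the truncated-sensory floor (~0.6)
  res0 <- run_offset_analgesia(levels = c(0, 0), n_replicates = 5,
                               seed = 12)
  expect_lt(max(abs(res0$interval_medians$median)), 1)
})

test_that("scenario runs are bit-reproducible from (config, seed)", {
  a <- run_offset_analgesia(n_replicates = 4, seed = 13)
  b <- run_offset_analgesia(n_replicates = 4, seed = 13)
  expect_identical(a$runs, b$runs)
  expect_identical(a$interval_medians, b$interval_medians)
  c1 <- run_conditioning_hier(n_individuals = 3, seed = 13)
  c2 <- run_conditioning_hier(n_individuals = 3, seed = 13)
  expect_identical(c1$trials, c2$trials)
})

test_that("toggling one noise stream does not shift the others", {
  sch <- impulse_schedule(50)
  with_p <- run_hier_filter(sch, hier_params(), seed = 14,
                            sample_param_noise = TRUE)
  without_p <- run_hier_filter(sch, hier_params(), seed = 14,
                               sample_param_noise = FALSE)
  expect_identical(with_p$z, without_p$z) # sensory stream untouched
})

test_that("tidy, glance and autoplot work across result families", {
  res <- run_chronic_pain(n_replicates = 4, n_steps = 80, seed = 15)
  expect_s3_class(tidy(res), "tbl_df")
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_s3_class(autoplot(res), "ggplot")
  pn <- run_placebo_nocebo_single(n_individuals = 3, seed = 15)
  expect_s3_class(autoplot(pn), "ggplot")
  off <- run_offset_analgesia(n_replicates = 3, seed = 15)
  expect_s3_class(autoplot(off), "ggplot")
})
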