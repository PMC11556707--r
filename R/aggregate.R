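#' Aggregate trajectories across replicates or individuals
#'
#' Replicate mode reports, per step, the median and interquartile range
#' (25-75% quantiles, linear-interpolation convention, `stats::quantile`
#' type 7) of a value across simulation runs — the reporting convention for
#' the truncation-skewed trajectory distributions. Individual mode reports,
#' per group, the mean and standard error `sd / sqrt(n)` across simulated
#' individuals.
#'
#' @param trajectories A tibble of stacked per-step (or per-trial) records
#'   holding a replicate/individual identifier.
#' @param mode `"replicate"` (median/IQR per step) or `"individual"`
#'   (mean/SE per group).
#' @param value Name of the value column to summarise (default `"x_hat"`).
#' @param by Grouping column(s): default `"step"` for replicate mode; for
#'   individual mode typically cell labels such as `c("cue", "heat")`.
#' @return A tibble with the grouping columns and either `median`, `q25`,
#'   `q75` (replicate mode) or `mean`, `se`, `n` (individual mode).
#' @export
#' @examples
#' tr <- tidyr::expand_grid(rep = 1:5, step = 1:3)
#' tr$x_hat <- tr$rep
#' aggregate_runs(tr, "replicate")
aggregate_runs <- function(trajectories, mode = c("replicate", "individual"),
                           value = "x_hat", by = "step") {
  mode <- match.arg(mode)
  if (nrow(trajectories) == 0) abort("no trajectories to aggregate.")
  v <- rlang::sym(value)
  g <- dplyr::group_by(trajectories, dplyr::across(dplyr::all_of(by)))
  if (mode == "replicate") {
    dplyr::summarise(
      g,
      median = median(!!v),
      q25 = quantile(!!v, 0.25, names = FALSE),
      q75 = quantile(!!v, 0.75, names = FALSE),
      .groups = "drop"
    )
  } else {
    dplyr::summarise(
      g,
      mean = mean(!!v),
      se = sd(!!v) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )
  }
}
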