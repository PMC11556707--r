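# Methods on scenario results: print, broom-style tidy()/glance(), and
# ggplot2 autoplot().

# The "primary" summary tibble of a result, by scenario family.
primary_summary <- function(x) {
  x$cells %||% x$interval_medians %||% x$trajectories %||% x$summary
}

#' @export
print.painkf_scenario <- function(x, ...) {
  cat(sprintf("<painkf_scenario: %s>  model = %s\n", x$name, x$model))
  cfg <- x$config
  scal <- cfg[vapply(cfg, function(v) is.atomic(v) && length(v) <= 3, TRUE)]
  cat("  config:", paste(names(scal),
                         vapply(scal, function(v) paste(format(v), collapse = "/"), ""),
                         sep = " = ", collapse = ", "), "\n")
  cat("  components:", paste(setdiff(names(x), c("name", "model", "config")),
                             collapse = ", "), "\n")
  s <- primary_summary(x)
  if (!is.null(s)) print(utils::head(tibble::as_tibble(s), 8))
  invisible(x)
}

#' Tidy a scenario result
#'
#' Returns the scenario's primary summary tibble: cue x heat cell means and
#' SEs for trial-based scenarios, interval medians for offset analgesia,
#' per-step median/IQR trajectories otherwise.
#'
#' @param x A `painkf_scenario`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy painkf_scenario
#' @export
tidy.painkf_scenario <- function(x, ...) {
  tibble::as_tibble(primary_summary(x))
}

#' One-row summary of a scenario result
#'
#' @param x A `painkf_scenario`.
#' @param ... Unused.
#' @method glance painkf_scenario
#' @return A one-row tibble with the scenario name, model, replicate
#'   counts, and the scenario's headline contrast where one is defined
#'   (e.g. the nocebo minus placebo gain separation, or the offset minus
#'   control T3_1 difference).
#' @export
glance.painkf_scenario <- function(x, ...) {
  out <- tibble::tibble(
    scenario = x$name, model = x$model,
    n = x$config$n_replicates %||% x$config$n_individuals %||% NA_integer_,
    seed = x$config$seed
  )
  if (x$name == "conditioning_hier") {
    last <- dplyr::filter(x$b_trajectories,
                          .data$trial == max(.data$trial))
    out$contrast <- last$median[last$gain == "nocebo"] -
      last$median[last$gain == "placebo"]
  } else if (x$name %in% c("placebo_nocebo_single")) {
    p <- dplyr::filter(x$cells, .data$measure == "perceived")
    out$contrast <- mean(p$mean[p$cue == "nocebo"]) -
      mean(p$mean[p$cue == "placebo"])
  } else if (x$name == "offset_analgesia") {
    m <- x$interval_medians
    out$contrast <-
      m$median[m$condition == "offset" & m$interval == "T3_1"] -
      m$median[m$condition == "control" & m$interval == "T3_1"]
  } else if (x$name == "chronic_pain" &&
             nrow(x$summary) > 0) {
    out$contrast <- max(x$summary$post_recovery_median_xhat) -
      min(x$summary$post_recovery_median_xhat)
  }
  out
}

#' Plot a scenario result
#'
#' Trajectory scenarios are drawn as a median line with an IQR ribbon
#' (faceted over the sweep cells where applicable); trial-based scenarios
#' as cell means with standard-error bars; offset analgesia as interval
#' medians with IQR bars for both conditions.
#'
#' @param object A `painkf_scenario`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot painkf_scenario
#' @export
autoplot.painkf_scenario <- function(object, ...) {
  nm <- object$name
  if (!is.null(object$cells)) {
    d <- dplyr::filter(object$cells, .data$measure == "perceived")
    return(
      ggplot2::ggplot(d, ggplot2::aes(x = .data$heat, y = .data$mean,
                                      colour = .data$cue,
                                      group = .data$cue)) +
        ggplot2::geom_point(size = 2) +
        ggplot2::geom_line() +
        ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                            ymax = .data$mean + .data$se),
                               width = 0.1) +
        ggplot2::labs(x = "heat level", y = "perceived pain (0-10)",
                      colour = "cue", title = nm)
    )
  }
  if (nm == "offset_analgesia") {
    d <- object$interval_medians
    return(
      ggplot2::ggplot(d, ggplot2::aes(x = .data$interval, y = .data$median,
                                      colour = .data$condition,
                                      group = .data$condition)) +
        ggplot2::geom_point(size = 2) +
        ggplot2::geom_line() +
        ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$q25,
                                            ymax = .data$q75),
                               width = 0.15) +
        ggplot2::labs(x = "assessment interval",
                      y = "perceived pain (interval median)",
                      title = nm)
    )
  }
  d <- object$trajectories
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.3, fill = "red") +
    ggplot2::geom_line(colour = "red") +
    ggplot2::labs(x = "time step", y = "median (IQR)", title = nm)
  facets <- intersect(c("variable", "history", "R_condition",
                        "A_hat_cell", "A0_cell", "R_cell"), names(d))
  if (length(facets) == 1) {
    p <- p + ggplot2::facet_wrap(facets, scales = "free_y")
  } else if (length(facets) >= 2) {
    p <- p + ggplot2::facet_grid(
      rows = ggplot2::vars(!!rlang::sym(facets[1])),
      cols = ggplot2::vars(!!rlang::sym(facets[2])),
      scales = "free_y"
    )
  }
  p
}
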