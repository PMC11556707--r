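# Configuration parsing, scenario dispatch, table writers and run
# manifests. Scenario configs are flat key = value text files; outputs are
# comma-separated tables (12 significant digits, so regression diffs stay
# meaningful) plus a JSON manifest that lets a run be reproduced bit-exactly.

.painkf_scenarios <- c("placebo_nocebo_single", "conditioning_hier",
                       "chronic_pain", "neuropathic_single_sweep",
                       "neuropathic_hier_sweep", "history_risk",
                       "offset_analgesia", "uncued_injury")

.painkf_hier_scenarios <- c("conditioning_hier", "neuropathic_hier_sweep",
                            "history_risk", "offset_analgesia")

# key -> expected type; "num_vec" accepts comma-separated numbers
.painkf_config_keys <- c(
  scenario = "chr", seed = "num", n_replicates = "num",
  n_individuals = "num", sample_process_noise = "lgl",
  sample_param_noise = "lgl", legacy_pp_update = "lgl",
  A_hat = "num", B_hat = "num_vec", H = "num", R = "num",
  Q0 = "num", Qu = "num", P0 = "num", Q_p = "num_vec", P_p0 = "num"
)

#' Parse a scenario configuration file
#'
#' Reads a flat `key = value` text file (`#` starts a comment). Unknown
#' keys are rejected by name; out-of-range values (e.g. `R <= 0`) raise a
#' range error; everything left unspecified is filled with the model's
#' default parameter values (`A_hat = 0.8`, `B_hat = 0.6`, `R = 0.8^2`,
#' `Q0 = 0.4^2` single-layer / `0.1^2` hierarchical, `Qu = 0.4^2`,
#' `P0 = 1e6`, `Q_p = 0.002^2` per entry, `P_p0 = 1e6`).
#'
#' @param path Path to the configuration file.
#' @return A named list of class `painkf_config` with `scenario`, `model`,
#'   `seed`, replicate counts, noise flags, and the full parameter
#'   snapshot.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      abort(sprintf("cannot parse config line (expected key = value): '%s'", ln))
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(.painkf_config_keys)) {
      abort(sprintf("unknown config key: '%s'", key))
    }
    kv[[key]] <- switch(
      .painkf_config_keys[[key]],
      chr = val,
      lgl = as.logical(val),
      num = {
        x <- suppressWarnings(as.numeric(val))
        if (is.na(x)) abort(sprintf("key '%s' must be numeric, got '%s'", key, val))
        x
      },
      num_vec = {
        x <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
        if (anyNA(x)) abort(sprintf("key '%s' must be numeric, got '%s'", key, val))
        x
      }
    )
  }
  scenario <- kv$scenario %||% "chronic_pain"
  if (!scenario %in% .painkf_scenarios) {
    abort(sprintf("unknown scenario '%s' (known: %s)", scenario,
                  paste(.painkf_scenarios, collapse = ", ")))
  }
  hier <- scenario %in% .painkf_hier_scenarios
  cfg <- list(
    scenario = scenario,
    model = if (hier) "hierarchical" else "single",
    seed = as.integer(kv$seed %||% 1),
    n_replicates = as.integer(kv$n_replicates %||% 100),
    n_individuals = as.integer(kv$n_individuals %||% 28),
    sample_process_noise = kv$sample_process_noise %||% TRUE,
    sample_param_noise = kv$sample_param_noise %||% TRUE,
    legacy_pp_update = kv$legacy_pp_update %||% FALSE,
    A_hat = kv$A_hat %||% 0.8,
    B_hat = kv$B_hat %||% 0.6,
    H = kv$H %||% 1,
    R = kv$R %||% 0.8^2,
    Q0 = kv$Q0 %||% (if (hier) 0.1^2 else 0.4^2),
    Qu = kv$Qu %||% 0.4^2,
    P0 = kv$P0 %||% 1e6,
    Q_p = kv$Q_p %||% 0.002^2,
    P_p0 = kv$P_p0 %||% 1e6
  )
  if (cfg$R <= 0) abort("config range error: `R` must be > 0.")
  if (cfg$Q0 < 0 || cfg$Qu < 0 || any(cfg$Q_p < 0)) {
    abort("config range error: variances must be >= 0.")
  }
  if (cfg$P0 <= 0 || cfg$P_p0 < 0) {
    abort("config range error: `P0` must be > 0 and `P_p0` >= 0.")
  }
  if (cfg$n_replicates < 1 || cfg$n_individuals < 1) {
    abort("config range error: replicate counts must be >= 1.")
  }
  structure(cfg, class = "painkf_config")
}

# Build the filter parameter object a config describes.
config_params <- function(cfg) {
  if (cfg$model == "hierarchical") {
    hier_params(A_hat = cfg$A_hat, B_hat = cfg$B_hat, H = cfg$H, R = cfg$R,
                Q0 = cfg$Q0, Qu = cfg$Qu, P0 = cfg$P0, Q_p = cfg$Q_p,
                P_p0 = cfg$P_p0, legacy_pp_update = cfg$legacy_pp_update)
  } else {
    filter_params(A_hat = cfg$A_hat, B_hat = cfg$B_hat, H = cfg$H,
                  R = cfg$R, Q0 = cfg$Q0, Qu = cfg$Qu, P0 = cfg$P0)
  }
}

#' Run a scenario from a parsed configuration
#'
#' Dispatches to the matching `run_*()` engine with the config's seed,
#' replicate counts, noise flags, and parameter overrides.
#'
#' @param config A `painkf_config` from [parse_config()].
#' @return A `painkf_scenario`.
#' @export
run_scenario <- function(config) {
  cfg <- config
  p <- config_params(cfg)
  switch(
    cfg$scenario,
    placebo_nocebo_single = run_placebo_nocebo_single(
      n_individuals = cfg$n_individuals, R = cfg$R, params = p,
      seed = cfg$seed, sample_process_noise = cfg$sample_process_noise
    ),
    conditioning_hier = run_conditioning_hier(
      n_individuals = cfg$n_individuals, R = cfg$R,
      Q0 = cfg$Q0, Qu = cfg$Qu, seed = cfg$seed,
      sample_process_noise = cfg$sample_process_noise,
      sample_param_noise = cfg$sample_param_noise
    ),
    chronic_pain = run_chronic_pain(
      n_replicates = cfg$n_replicates, A_hat = cfg$A_hat, params = p,
      seed = cfg$seed, sample_process_noise = cfg$sample_process_noise
    ),
    neuropathic_single_sweep = run_neuropathic_single_sweep(
      n_replicates = cfg$n_replicates, params = p, seed = cfg$seed,
      sample_process_noise = cfg$sample_process_noise
    ),
    neuropathic_hier_sweep = run_neuropathic_hier_sweep(
      n_replicates = cfg$n_replicates, params = p, seed = cfg$seed,
      sample_process_noise = cfg$sample_process_noise,
      sample_param_noise = cfg$sample_param_noise
    ),
    history_risk = run_history_risk(
      n_replicates = cfg$n_replicates, params = p, seed = cfg$seed,
      sample_process_noise = cfg$sample_process_noise,
      sample_param_noise = cfg$sample_param_noise
    ),
    offset_analgesia = run_offset_analgesia(
      n_replicates = cfg$n_replicates, R = cfg$R, params = p,
      seed = cfg$seed,
      sample_process_noise = cfg$sample_process_noise,
      sample_param_noise = cfg$sample_param_noise
    ),
    uncued_injury = run_uncued_injury(
      n_replicates = cfg$n_replicates, R = cfg$R, A_hat = cfg$A_hat,
      params = p, seed = cfg$seed,
      sample_process_noise = cfg$sample_process_noise
    )
  )
}

#' Build a run manifest
#'
#' Records the scenario name, seed, the full effective parameter snapshot,
#' package version and timestamp, plus a hash of the reproducibility-
#' relevant fields (everything except the timestamp): rerunning from the
#' manifest's snapshot reproduces the run bit-exactly, and the hash changes
#' iff an effective parameter changes.
#'
#' @param result A `painkf_scenario`.
#' @return A list of class `painkf_manifest`.
#' @export
run_manifest <- function(result) {
  snapshot <- result$config
  core <- list(scenario = result$name, model = result$model,
               parameters = snapshot)
  structure(
    c(core,
      list(config_hash = rlang::hash(core),
           package_version = as.character(packageVersion("painkf")),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "painkf_manifest"
  )
}

# Format numeric columns at 12 significant digits and write CSV.
write_output_table <- function(df, path) {
  out <- as.data.frame(df)
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = 12, format = "g")
    } else if (is.list(out[[j]])) {
      out[[j]] <- vapply(out[[j]], function(v)
        paste(formatC(v, digits = 12, format = "g"), collapse = ";"), "")
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an output table
#'
#' @param path Path to a table written by [write_outputs()].
#' @return A tibble with numeric columns re-parsed.
#' @export
read_output_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    fileEncoding = "UTF-8"))
}

#' Write scenario outputs to a directory
#'
#' Writes the per-step/per-trial trajectory table, the summary table, and
#' the JSON run manifest. Numbers are serialised with 12 significant
#' digits.
#'
#' @param result A `painkf_scenario`.
#' @param outdir Output directory (created if missing).
#' @param manifest Optional pre-built manifest (default
#'   `run_manifest(result)`).
#' @return Invisibly, the named character vector of file paths written.
#' @export
write_outputs <- function(result, outdir, manifest = run_manifest(result)) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok) abort(sprintf("cannot create output directory: %s", outdir))
  traj <- result$runs %||% result$trials
  summ <- primary_summary(result)
  paths <- c(
    trajectories = file.path(outdir, sprintf("%s_trajectories.csv", result$name)),
    summary = file.path(outdir, sprintf("%s_summary.csv", result$name)),
    manifest = file.path(outdir, sprintf("%s_manifest.json", result$name))
  )
  tryCatch({
    write_output_table(traj, paths[["trajectories"]])
    write_output_table(summ, paths[["summary"]])
    jsonlite::write_json(unclass(manifest), paths[["manifest"]],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, error = function(e) {
    abort(sprintf("failed writing outputs under '%s': %s", outdir,
                  conditionMessage(e)))
  })
  invisible(paths)
}

#' Load an external trial-level rating table
#'
#' Optional comparison loader for delimited-text rating tables with
#' columns `individual`, `trial`, `cue`, `temperature`, `expected_rating`,
#' `pain_rating`, with ratings on a 100-unit visual-analogue scale. The
#' table is validated for side-by-side plotting against simulated cells;
#' nothing in the package requires it.
#'
#' @param path Path to a comma- or tab-delimited text file with a header.
#' @return A tibble.
#' @export
load_rating_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("rating table not found: %s", path))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  required <- c("individual", "trial", "cue", "temperature",
                "expected_rating", "pain_rating")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("rating table schema error: missing column(s) %s",
                  paste(sprintf("'%s'", missing), collapse = ", ")))
  }
  ratings <- c(df$expected_rating, df$pain_rating)
  if (any(ratings < 0 | ratings > 100, na.rm = TRUE)) {
    warning("rating(s) outside the 100-unit scale [0, 100].", call. = FALSE)
  }
  tibble::as_tibble(df)
}
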