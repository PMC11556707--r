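# Seed plumbing.
#
# Each replicate owns independent noise streams (sensory, process, parameter,
# individual-level draws), each seeded by a deterministic hash of
# (seed, replicate, stream). Toggling one noise source therefore never shifts
# the draws of another, and a run is bit-reproducible from (config, seed).

.painkf_streams <- c(sensory = 1L, process = 2L, param = 3L, individual = 4L)

#' Derive a stream seed
#'
#' Deterministically maps `(seed, replicate, stream)` to a seed below
#' `2^31 - 1`. All multipliers keep intermediate products inside the exactly
#' representable double range.
#'
#' @param seed Base integer seed.
#' @param replicate Replicate (or individual) index, `>= 1`.
#' @param stream One of `"sensory"`, `"process"`, `"param"`, `"individual"`.
#' @return A single integer seed.
#' @export
stream_seed <- function(seed, replicate, stream) {
  sid <- .painkf_streams[[match.arg(stream, names(.painkf_streams))]]
  h <- (abs(seed) %% 2147483647) * 1000003 + replicate * 10007 + sid * 101
  as.integer(h %% 2147483629) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded by `seed`.
with_stream_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Standard-normal draw tables for one replicate: the engines scale these by
# the step-wise standard deviations, so switching a noise flag off simply
# drops the term without consuming different draws elsewhere.
draw_noise_streams <- function(seed, replicate, n_steps, d_param) {
  list(
    process = with_stream_seed(stream_seed(seed, replicate, "process"),
                               rnorm(n_steps)),
    param = with_stream_seed(stream_seed(seed, replicate, "param"),
                             matrix(rnorm(n_steps * d_param), nrow = n_steps))
  )
}
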