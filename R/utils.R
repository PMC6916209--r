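#' @keywords internal
#' @importFrom ggplot2 .data
"_PACKAGE"

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# user's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed fan-out from one global seed. Offsets are
# fixed per stage name so each stage is independently reproducible; result
# kept inside 32-bit integer range.
stage_seed <- function(seed, stage) {
  stages <- c(
    simulate = 11L, encode = 23L, train = 37L, featurize = 41L,
    baseline = 53L, eval = 67L, heatmap = 79L, sweep = 83L
  )
  off <- stages[[stage]]
  if (is.null(off)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 1009 + off) %% .Machine$integer.max)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a
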