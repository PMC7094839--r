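# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a per-stage RNG seed from a global seed
#'
#' Counter-based: each (seed, stage) pair maps to a distinct stream, so
#' adding a stage never perturbs the draws of earlier stages and sweeps
#' over consecutive global seeds never collide across stages. Result stays
#' below 2^31.
#'
#' @param seed global integer seed.
#' @param stage one of `"thickness"`, `"simulate"`, `"univariate"`,
#'   `"variance"`, `"pattern"`, `"bootstrap"`, `"recover"`.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  # multiplier 7 with offsets 0..6 makes (seed, stage) -> stream injective:
  # two different (seed, stage) pairs can never share an RNG stream
  offsets <- c(thickness = 0L, simulate = 1L, univariate = 2L, variance = 3L,
               pattern = 4L, bootstrap = 5L, recover = 6L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 7L + offsets[[stage]]) %% 2147483647)
}

# Sample standard deviation of each row of a matrix (n - 1 denominator).
row_sds <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}

# Numbers written so that read.csv reproduces the double bit-for-bit.
full_precision <- function(x) {
  if (is.numeric(x)) sprintf("%.17g", x) else x
}
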