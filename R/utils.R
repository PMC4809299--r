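#' Derive a child seed from a base seed
#'
#' Deterministic counter scheme used to fan a single user-supplied seed out
#' to per-stage and per-run streams: each pipeline stage has a fixed integer
#' offset and each repetition an index.  Children stay below 2^31 so they are
#' always valid inputs to [set.seed()].
#'
#' @param base integer base seed.
#' @param stage integer stage offset (each stage of the pipeline uses its own
#'   constant; see [pipeline_stage_offsets()]).
#' @param index integer repetition counter within the stage (0-based).
#' @return a single integer seed.
#' @export
derive_seed <- function(base, stage = 0L, index = 0L) {
  base <- as.double(base)
  if (!is.finite(base)) stop("`base` seed must be a finite number")
  ((base %% 1000003) * 1009 + stage * 7919 + index) %% 2147483647
}

#' Stage offsets used by the pipeline seed scheme
#'
#' @return named integer vector of the fixed stage offsets.
#' @export
pipeline_stage_offsets <- function() {
  c(map = 1L, genotypes = 2L, qtl = 3L, phenotypes = 4L,
    weather = 5L, cv = 6L)
}

# run `expr` with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so library code never clobbers user RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# round half away from zero (SAS-style), used for the 80% training counts
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
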