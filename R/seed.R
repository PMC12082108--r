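#' Derive a stage-specific seed from a master seed
#'
#' All randomness in the package flows from a single master seed. Each
#' stochastic stage (trajectories, colonies, junctions, bootstrap, ...)
#' re-seeds the RNG with a deterministic function of the master seed and a
#' stage label, so stages can be re-run independently and adding draws to
#' one stage never perturbs another.
#'
#' The scheme is a fixed affine map modulo the Mersenne prime 2^31 - 1:
#' `(seed * 48271 + offset(stream)) mod (2^31 - 1)`, with one reserved
#' offset per stage name.
#'
#' @param seed Integer master seed.
#' @param stream Stage label, one of `"trajectories"`, `"colonies"`,
#'   `"junctions"`, `"bootstrap"`, `"pipeline"`, or an integer offset.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  offsets <- c(trajectories = 1, colonies = 2, junctions = 3,
               bootstrap = 4, pipeline = 5)
  off <- if (is.character(stream)) {
    if (!stream %in% names(offsets)) stop("unknown seed stream: ", stream)
    offsets[[stream]]
  } else {
    as.numeric(stream)
  }
  as.integer((as.numeric(seed) * 48271 + off) %% 2147483647)
}
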