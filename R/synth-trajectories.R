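#' Deterministic clone fractions under replicator dynamics
#'
#' Solves `df_i/dt = f_i (s_i - sum_j f_j s_j)` exactly, with wild type as
#' the implicit reference clone at s = 0: the solution is the normalized
#' exponential weighting `f_i(t) = f_i(0) exp(s_i t) / [f_WT(0) +
#' sum_j f_j(0) exp(s_j t)]`.
#'
#' @param times_years Numeric vector of times (years).
#' @param s Named per-clone selection coefficients (per year).
#' @param f0 Named per-clone fractions at t = 0 (wild type is the
#'   remainder).
#' @return Matrix `length(times) x (clones + WT)` of cell fractions; rows
#'   sum to 1.
#' @export
clone_fractions <- function(times_years, s, f0) {
  stopifnot(length(s) == length(f0), all(f0 >= 0), sum(f0) <= 1)
  fw0 <- 1 - sum(f0)
  w <- outer(times_years, s, function(t, si) exp(si * t))
  w <- sweep(w, 2, f0, `*`)
  z <- fw0 + rowSums(w)
  f <- cbind(w / z, WT = fw0 / z)
  colnames(f) <- c(names(s), "WT")
  if (any(!is.finite(f)) || any(f < -1e-12) || any(f > 1 + 1e-12))
    stop("clone fractions escaped [0,1]: integration failure")
  pmin(pmax(f, 0), 1)
}

#' Simulate longitudinal ddPCR VAF trajectories for competing clones
#'
#' Propagates clone fractions deterministically under replicator dynamics
#' (see [clone_fractions()]), converts to VAF assuming heterozygous
#' diploid variants (VAF = fraction / 2), and observes each visit through
#' binomial droplet counting: `mutant droplets ~ Binom(droplets, VAF)`.
#' Observed VAFs below the detection limit are flagged censored.
#'
#' @param config A [simulation_config()].
#' @return List with `vaf` (long data.frame: `variant`, `time_months`,
#'   `vaf`, `droplets`, `censored`) and `truth` (selection coefficients,
#'   true fraction/VAF trajectories, seed).
#' @export
simulate_clonal_trajectories <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, "trajectories"))
  tm <- config$sampling_times
  f <- clone_fractions(tm / 12, config$selection_coeffs,
                       config$initial_fractions)
  vaf_true <- f[, config$clones, drop = FALSE] / 2
  n <- config$droplets_per_assay
  obs <- matrix(stats::rbinom(length(vaf_true), n, as.vector(vaf_true)) / n,
                nrow = nrow(vaf_true), dimnames = dimnames(vaf_true))
  vaf <- data.frame(
    variant = rep(config$clones, each = length(tm)),
    time_months = rep(tm, times = length(config$clones)),
    vaf = as.vector(obs),
    droplets = n,
    censored = as.vector(obs) < config$detection_limit,
    stringsAsFactors = FALSE
  )
  truth <- list(
    selection_coeffs = config$selection_coeffs,
    initial_fractions = config$initial_fractions,
    fractions = data.frame(time_months = rep(tm, ncol(f)),
                           clone = rep(colnames(f), each = length(tm)),
                           fraction = as.vector(f)),
    vaf_true = data.frame(time_months = rep(tm, ncol(vaf_true)),
                          variant = rep(colnames(vaf_true), each = length(tm)),
                          vaf = as.vector(vaf_true)),
    seed = config$seed
  )
  list(vaf = vaf, truth = truth)
}
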