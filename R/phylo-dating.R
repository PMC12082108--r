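#' Estimate the somatic mutation rate from colony burdens and ages
#'
#' Fits a Poisson regression of mutation burden on donor age through the
#' origin (clock-like accrual: `burden_i ~ Poisson(rate x age_i)`).  The
#' maximum-likelihood rate is total burden over total age; the 95%
#' interval is the exact gamma (Poisson) interval on the total count
#' scaled by total age, which coincides with the profile-likelihood
#' interval of the offset regression.  Optional `groups` stratify the
#' estimate (e.g. mutant clones vs wild-type colonies).
#'
#' @param burdens Per-colony mutation counts.
#' @param ages Per-colony donor ages at sampling (years).
#' @param groups Optional per-colony stratum labels.
#' @param conf Confidence level (default 0.95).
#' @return data.frame with `group`, `rate` (per year), `lower`, `upper`,
#'   `total_burden`, `total_age`.
#' @export
estimate_mutation_rate <- function(burdens, ages, groups = NULL,
                                   conf = 0.95) {
  stopifnot(length(burdens) == length(ages), all(burdens >= 0),
            all(ages >= 0))
  if (all(ages == 0)) stop("all ages zero: rate undefined")
  if (is.null(groups)) groups <- rep("all", length(burdens))
  alpha <- 1 - conf
  out <- lapply(split(seq_along(burdens), groups), function(idx) {
    x <- sum(burdens[idx]); tt <- sum(ages[idx])
    if (tt <= 0) stop("stratum with zero total age")
    lower <- if (x == 0) 0 else stats::qgamma(alpha / 2, x) / tt
    data.frame(rate = x / tt, lower = lower,
               upper = stats::qgamma(1 - alpha / 2, x + 1) / tt,
               total_burden = x, total_age = tt)
  })
  res <- do.call(rbind, out)
  res <- cbind(group = names(out), res)
  rownames(res) <- NULL
  res
}

#' Date the acquisition of a driver mutation on a clone tree
#'
#' Under a linear molecular clock, the driver was acquired somewhere on
#' its branch: after the `m_before` mutations carried by ancestral
#' branches and no later than the `m_through = m_before + branch length`
#' mutations accumulated through the end of its own branch.  Both counts
#' are converted to years by dividing by the clock rate; 95% bounds widen
#' each endpoint with the exact Poisson count interval (gamma quantiles)
#' before conversion, and the upper bound is clamped to the donor age at
#' sampling.  The point estimate is the branch midpoint in mutation time.
#'
#' @param tree A `clone_tree` from [build_clone_tree()].
#' @param rate Clock rate in mutations per year (> 0).
#' @param driver Mutation id to date.
#' @param age_at_sampling Donor age (years); upper clamp.
#' @param conf Confidence level (default 0.95).
#' @return data.frame (class `age_interval`): `mutation`,
#'   `lower_bound_years`, `point_estimate_years`, `upper_bound_years`,
#'   `conf`.
#' @export
date_acquisition <- function(tree, rate, driver, age_at_sampling,
                             conf = 0.95) {
  stopifnot(inherits(tree, "clone_tree"), rate > 0, age_at_sampling > 0)
  hit <- names(tree$mutations)[vapply(tree$mutations,
                                      function(m) driver %in% m, TRUE)]
  if (length(hit) == 0) stop("driver '", driver, "' absent from tree")
  if (length(hit) > 1)
    stop("driver '", driver, "' on multiple incomparable branches")
  node <- hit
  m_before <- 0L
  p <- tree$nodes$parent[tree$nodes$id == node]
  while (!is.na(p) && p != "root") {
    m_before <- m_before + tree$nodes$n_mutations[tree$nodes$id == p]
    p <- tree$nodes$parent[tree$nodes$id == p]
  }
  m_through <- m_before + tree$nodes$n_mutations[tree$nodes$id == node]
  alpha <- 1 - conf
  lower <- if (m_before == 0) 0 else stats::qgamma(alpha / 2, m_before) / rate
  upper <- stats::qgamma(1 - alpha / 2, m_through + 1) / rate
  point <- (m_before + m_through) / 2 / rate
  upper <- min(upper, age_at_sampling)
  point <- min(point, upper)
  lower <- min(lower, point)
  structure(data.frame(mutation = driver,
                       lower_bound_years = lower,
                       point_estimate_years = point,
                       upper_bound_years = upper,
                       conf = conf, stringsAsFactors = FALSE),
            class = c("age_interval", "data.frame"))
}
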