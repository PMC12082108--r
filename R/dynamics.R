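#' Convert a variant allele frequency to a mutant cell fraction
#'
#' For a heterozygous variant in a diploid region, half the alleles of a
#' mutant cell are mutant, so the cell fraction is twice the VAF, clamped
#' at 1.  Other zygosity/copy-number models are deliberately unsupported.
#'
#' @param vaf Numeric VAF(s) in `[0, 1]`.
#' @param zygosity Only `"heterozygous"` is supported.
#' @param copy_number Only 2 is supported.
#' @return Cell fraction(s) in `[0, 1]`.
#' @export
vaf_to_cell_fraction <- function(vaf, zygosity = "heterozygous",
                                 copy_number = 2L) {
  if (!identical(zygosity, "heterozygous") || copy_number != 2L)
    stop("unsupported zygosity/copy-number model: only heterozygous diploid")
  if (any(vaf < 0 | vaf > 1, na.rm = TRUE)) stop("vaf must lie in [0,1]")
  pmin(1, 2 * vaf)
}

#' Exact binomial enrichment test for colony genotype counts
#'
#' Tests whether `k` colonies of a given genotype out of `n` genotyped
#' colonies are compatible with an expected fraction `p0` (typically twice
#' the contemporaneous bulk VAF, i.e. the heterozygous-diploid cell
#' fraction), using exact binomial tail probabilities.  The two-sided
#' p-value is twice the smaller tail, capped at 1.
#'
#' @param k Colonies carrying the genotype.
#' @param n Total genotyped colonies (> 0).
#' @param expected_fraction Null genotype fraction in `[0, 1]`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return Object of class `colony_enrichment_result`: a list with `k_clone`,
#'   `n_total`, `expected_fraction`, `alternative`, `p_value`.
#' @export
colony_enrichment_test <- function(k, n, expected_fraction,
                                   alternative = c("two.sided", "greater",
                                                   "less")) {
  alternative <- match.arg(alternative)
  if (n <= 0) stop("undefined test: n must be positive")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  if (expected_fraction < 0 || expected_fraction > 1)
    stop("expected_fraction must lie in [0,1]")
  upper <- stats::pbinom(k - 1, n, expected_fraction, lower.tail = FALSE)
  lower <- stats::pbinom(k, n, expected_fraction)
  p <- switch(alternative,
              greater = upper,
              less = lower,
              two.sided = min(1, 2 * min(lower, upper)))
  structure(list(k_clone = as.integer(k), n_total = as.integer(n),
                 expected_fraction = expected_fraction,
                 alternative = alternative, p_value = p),
            class = "colony_enrichment_result")
}

#' @export
print.colony_enrichment_result <- function(x, ...) {
  cat(sprintf("colony enrichment: %d/%d vs expected %.3f (%s): p = %.3g\n",
              x$k_clone, x$n_total, x$expected_fraction, x$alternative,
              x$p_value))
  invisible(x)
}

# model-predicted VAFs for parameter vector par = c(s_1..s_K, a_1..a_K),
# where f0 = exp(a) / (1 + sum(exp(a))) keeps fractions in the simplex
.competition_predict <- function(par, clones, times_years) {
  k <- length(clones)
  s <- par[seq_len(k)]
  ea <- exp(par[k + seq_len(k)])
  f0 <- ea / (1 + sum(ea))
  names(s) <- names(f0) <- clones
  f <- clone_fractions(times_years, s, f0)
  list(s = s, f0 = f0, vaf = f[, clones, drop = FALSE] / 2)
}

.competition_objective <- function(par, clones, dat, detection_limit) {
  pred <- try(.competition_predict(par, clones, sort(unique(dat$time_years))),
              silent = TRUE)
  if (inherits(pred, "try-error")) return(1e6)
  tt <- sort(unique(dat$time_years))
  idx <- match(dat$time_years, tt)
  mu <- pred$vaf[cbind(idx, match(dat$variant, clones))]
  r <- ifelse(dat$censored, pmax(0, mu - detection_limit), mu - dat$vaf)
  sum(r^2)
}

#' Fit the clonal-competition (replicator) model to VAF trajectories
#'
#' Least-squares fit of the replicator model used by
#' [simulate_clonal_trajectories()] to observed VAF series: estimates a
#' selection coefficient per clone (per year, wild type fixed at 0) and
#' the initial cell fractions.  Observations flagged censored (below the
#' ddPCR detection floor) contribute a one-sided penalty only when the
#' model exceeds the floor.  Uncertainty comes from a seeded parametric
#' bootstrap: droplet counts are redrawn from the fitted trajectory and
#' the model refit.
#'
#' @param vaf Long data.frame with columns `variant`, `time_months`,
#'   `vaf`, and optionally `droplets` and `censored`.
#' @param detection_limit VAF floor for censored observations.
#' @param n_boot Bootstrap replicates for standard errors (0 to skip).
#' @param seed Seed for the bootstrap stream.
#' @return Object of class `competition_fit`: selection coefficients `s`,
#'   bootstrap `se`, `initial_fractions`, residual sum of squares `rss`,
#'   fitted trajectories, convergence code.
#' @export
fit_competition_model <- function(vaf, detection_limit = 0.001,
                                  n_boot = 200L, seed = 1L) {
  need <- c("variant", "time_months", "vaf")
  if (!all(need %in% names(vaf))) stop("vaf table missing columns")
  if (is.null(vaf$censored)) vaf$censored <- vaf$vaf < detection_limit
  if (is.null(vaf$droplets)) vaf$droplets <- 10000L
  clones <- unique(vaf$variant)
  per_clone <- table(vaf$variant)
  if (any(per_clone < 2) || nrow(vaf) < 3)
    stop("non-identifiable: need >= 2 visits per clone and >= 3 overall")
  dat <- data.frame(variant = vaf$variant,
                    time_years = vaf$time_months / 12,
                    vaf = vaf$vaf, censored = vaf$censored,
                    droplets = vaf$droplets)
  k <- length(clones)
  first <- dat[!duplicated(dat$variant), ]
  f0_start <- pmin(pmax(2 * first$vaf[match(clones, first$variant)], 1e-4),
                   0.9 / k)
  a_start <- log(f0_start / (1 - sum(f0_start)))
  start <- c(rep(0, k), a_start)
  fit1 <- function(d, st) {
    o <- stats::optim(st, .competition_objective, clones = clones, dat = d,
                      detection_limit = detection_limit, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
    o2 <- stats::optim(o$par, .competition_objective, clones = clones,
                       dat = d, detection_limit = detection_limit,
                       method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
    if (o2$value < o$value) o2 else o
  }
  opt <- fit1(dat, start)
  pred <- .competition_predict(opt$par, clones, sort(unique(dat$time_years)))
  se <- stats::setNames(rep(NA_real_, k), clones)
  boot_s <- NULL
  if (n_boot > 0) {
    set.seed(derive_seed(seed, "bootstrap"))
    tt <- sort(unique(dat$time_years))
    mu <- pred$vaf[cbind(match(dat$time_years, tt),
                         match(dat$variant, clones))]
    boot_s <- matrix(NA_real_, n_boot, k, dimnames = list(NULL, clones))
    for (b in seq_len(n_boot)) {
      db <- dat
      db$vaf <- stats::rbinom(nrow(dat), dat$droplets, mu) / dat$droplets
      db$censored <- db$vaf < detection_limit
      ob <- stats::optim(opt$par, .competition_objective, clones = clones,
                         dat = db, detection_limit = detection_limit,
                         method = "BFGS",
                         control = list(maxit = 200, reltol = 1e-10))
      boot_s[b, ] <- ob$par[seq_len(k)]
    }
    se <- apply(boot_s, 2, stats::sd)
  }
  fitted <- data.frame(
    time_months = rep(sort(unique(dat$time_years)) * 12, k),
    variant = rep(clones, each = length(unique(dat$time_years))),
    vaf = as.vector(pred$vaf))
  structure(list(s = pred$s, se = se, initial_fractions = pred$f0,
                 rss = opt$value, fitted = fitted,
                 convergence = opt$convergence, n_boot = n_boot,
                 boot_s = boot_s),
            class = "competition_fit")
}

#' @export
print.competition_fit <- function(x, ...) {
  cat("competition fit (replicator model, WT s = 0):\n")
  for (cl in names(x$s))
    cat(sprintf("  %s: s = %.4f /yr (se %.4f), f0 = %.4f\n",
                cl, x$s[[cl]], x$se[[cl]], x$initial_fractions[[cl]]))
  cat(sprintf("  rss = %.3g, convergence = %d\n", x$rss, x$convergence))
  invisible(x)
}

#' Detect the frequency inversion point of two VAF trajectories
#'
#' Linearly interpolates both series on their shared observation window
#' and returns the earliest time (months) at which they cross.  If the
#' series are identical over the window, the earliest shared time is
#' returned (documented tie rule); if they never cross, `NA`.
#'
#' @param seriesA,seriesB data.frames with columns `time_months`, `vaf`.
#' @return Crossing time in months, or `NA_real_` if none.
#' @export
detect_inversion <- function(seriesA, seriesB) {
  for (s in list(seriesA, seriesB))
    if (!all(c("time_months", "vaf") %in% names(s)))
      stop("series need time_months and vaf columns")
  lo <- max(min(seriesA$time_months), min(seriesB$time_months))
  hi <- min(max(seriesA$time_months), max(seriesB$time_months))
  if (lo > hi) stop("observation windows do not overlap")
  grid <- sort(unique(c(seriesA$time_months, seriesB$time_months)))
  grid <- grid[grid >= lo & grid <= hi]
  a <- stats::approx(seriesA$time_months, seriesA$vaf, xout = grid)$y
  b <- stats::approx(seriesB$time_months, seriesB$vaf, xout = grid)$y
  d <- a - b
  tol <- 1e-12
  if (all(abs(d) < tol)) return(grid[1])
  for (i in seq_along(d)) {
    if (abs(d[i]) < tol) return(grid[i])
    if (i < length(d) && sign(d[i]) != sign(d[i + 1]) && abs(d[i + 1]) >= tol)
      return(grid[i] + d[i] * (grid[i + 1] - grid[i]) / (d[i] - d[i + 1]))
  }
  NA_real_
}
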