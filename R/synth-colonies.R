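#' Construct a binary colony-by-variant mutation matrix
#'
#' Thin S3 container pairing a sparse 0/1 colony x variant matrix with
#' per-colony metadata (compartment, donor age) and an optional index of
#' missing (not genotyped) entries.  Missing entries are treated as
#' uninformative downstream: they join neither the carrier nor the
#' non-carrier set of a variant.
#'
#' @param mat Matrix-like (base matrix possibly containing `NA`, or a
#'   `Matrix` sparse matrix), colonies as rows, variants as columns.
#' @param compartment Per-colony compartment labels.
#' @param age_years Per-colony donor age at sampling (years).
#' @param missing Optional 2-column integer matrix of (row, col) missing
#'   positions; inferred from `NA`s when `mat` is a base matrix.
#' @return Object of class `mutation_matrix`.
#' @export
mutation_matrix <- function(mat, compartment = NULL, age_years = NULL,
                            missing = NULL) {
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("colony%03d", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("var%03d", seq_len(ncol(mat)))
  if (anyDuplicated(colnames(mat))) stop("variant ids must be unique")
  if (is.matrix(mat)) {
    if (is.null(missing) && anyNA(mat))
      missing <- which(is.na(mat), arr.ind = TRUE)[, 1:2, drop = FALSE]
    mat[is.na(mat)] <- 0
    sm <- methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE),
                                  "generalMatrix"), "CsparseMatrix")
  } else {
    sm <- methods::as(mat, "CsparseMatrix")
  }
  if (!is.null(missing)) {
    missing <- as.matrix(missing)
    if (nrow(missing) > 0) {
      obs_per_colony <- ncol(sm) - tabulate(missing[, 1], nbins = nrow(sm))
      if (any(obs_per_colony == 0)) stop("colony with all entries missing")
    }
  }
  structure(list(matrix = sm,
                 colonies = rownames(sm), variants = colnames(sm),
                 compartment = compartment, age_years = age_years,
                 missing = missing),
            class = "mutation_matrix")
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat("mutation_matrix:", nrow(x$matrix), "colonies x", ncol(x$matrix),
      "variants;", if (is.null(x$missing)) 0 else nrow(x$missing),
      "missing entries\n")
  invisible(x)
}

#' @export
dim.mutation_matrix <- function(x) dim(x$matrix)

# per-variant carrier sets (colony indices with an observed 1)
.carrier_sets <- function(mm) {
  m <- mm$matrix
  tr <- Matrix::summary(m)
  tr <- tr[tr$x != 0, , drop = FALSE]
  sets <- split(tr$i, factor(tr$j, levels = seq_len(ncol(m))))
  names(sets) <- colnames(m)
  lapply(sets, sort)
}

#' Per-colony observed mutation burden
#'
#' @param mm A [mutation_matrix()].
#' @return Named integer vector of per-colony counts of observed 1s.
#' @export
mutation_burden <- function(mm) {
  stopifnot(inherits(mm, "mutation_matrix"))
  stats::setNames(as.integer(Matrix::rowSums(mm$matrix)), mm$colonies)
}

#' Simulate compartment-sorted colony genotypes with mutation accrual
#'
#' Per sorted compartment, colony genotypes (clone A, clone B, ..., WT)
#' are drawn multinomially from the configured clone fractions.  Each
#' clone founds at an acquisition age drawn uniformly from
#' `acquisition_bounds` (or fixed via `acquisition_times`); its trunk
#' carries the clone's driver plus `Poisson(rate x acquisition age)`
#' co-mutations shared by every colony of the clone.  Each colony
#' additionally carries private `Poisson(rate x (age - acquisition age))`
#' mutations (WT colonies: `Poisson(rate x age)`), implementing a linear
#' molecular clock.
#'
#' @param config A [simulation_config()].
#' @return List with `genotypes` (data.frame: colony, compartment, clone,
#'   age_years, n_trunk, n_private), `matrix` (a [mutation_matrix()]),
#'   and `truth` (acquisition ages, trunk mutation sets, expected
#'   genotype fractions, seed).
#' @export
simulate_colonies <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, "colonies"))
  rate <- config$mutation_rate_per_year
  age <- config$age_at_diagnosis + config$colony_sampling_month / 12
  clones <- config$clones
  k <- length(clones)
  t_acq <- config$acquisition_times
  if (is.null(t_acq))
    t_acq <- stats::runif(k, config$acquisition_bounds[1],
                          min(config$acquisition_bounds[2], age))
  names(t_acq) <- clones
  # shared trunk per clone: the driver plus clocklike co-mutations
  trunk <- lapply(clones, function(cl) {
    n_co <- stats::rpois(1, rate * t_acq[[cl]])
    c(paste0("driver_", cl),
      if (n_co > 0) sprintf("trunk_%s_%03d", cl, seq_len(n_co)))
  })
  names(trunk) <- clones
  rows <- list()
  for (comp in names(config$compartments)) {
    fr <- config$compartments[[comp]]
    probs <- c(fr, WT = 1 - sum(fr))
    g <- sample(names(probs), config$colonies_per_compartment,
                replace = TRUE, prob = probs)
    rows[[comp]] <- data.frame(
      colony = sprintf("%s_c%03d", comp,
                       seq_len(config$colonies_per_compartment)),
      compartment = comp, clone = g, stringsAsFactors = FALSE)
  }
  geno <- do.call(rbind, rows)
  rownames(geno) <- NULL
  geno$age_years <- age
  n_col <- nrow(geno)
  priv_rate <- ifelse(geno$clone == "WT", rate * age,
                      rate * (age - t_acq[geno$clone]))
  n_priv <- stats::rpois(n_col, priv_rate)
  priv_ids <- lapply(seq_len(n_col), function(i)
    if (n_priv[i] > 0) sprintf("priv_%s_%04d", geno$colony[i],
                               seq_len(n_priv[i])))
  all_vars <- c(unlist(trunk, use.names = FALSE),
                unlist(priv_ids, use.names = FALSE))
  var_index <- stats::setNames(seq_along(all_vars), all_vars)
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n_col)) {
    muts <- c(if (geno$clone[i] != "WT") trunk[[geno$clone[i]]],
              priv_ids[[i]])
    if (length(muts)) {
      ii <- c(ii, rep.int(i, length(muts)))
      jj <- c(jj, var_index[muts])
    }
  }
  sm <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                             dims = c(n_col, length(all_vars)),
                             dimnames = list(geno$colony, all_vars))
  mm <- mutation_matrix(sm, compartment = geno$compartment,
                        age_years = geno$age_years)
  geno$n_trunk <- ifelse(geno$clone == "WT", 0L,
                         lengths(trunk)[geno$clone])
  geno$n_private <- n_priv
  truth <- list(acquisition_ages = t_acq, trunk = trunk,
                expected_fractions = lapply(config$compartments, function(fr)
                  c(fr, WT = 1 - sum(fr))),
                seed = config$seed)
  list(genotypes = geno, matrix = mm, truth = truth)
}
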