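#' Selection coefficients solved from the index patient's endpoint VAFs
#'
#' Under replicator dynamics with wild type as the s = 0 reference, the
#' log ratio of a clone's fraction to the wild-type fraction changes
#' linearly at rate s.  Given VAF endpoints for two clones at diagnosis and
#' after `years` of follow-up, the per-clone selection coefficients have the
#' closed form `s_i = log[(f_i(T)/f_WT(T)) / (f_i(0)/f_WT(0))] / T`.
#'
#' Defaults are the index patient's reported trajectory: clone A 43% -> 0%
#' VAF (taken at a 0.1% ddPCR detection floor) and clone B 4.6% -> 41% VAF
#' over 14 years, heterozygous diploid (cell fraction = 2 x VAF).
#'
#' @param vaf0 Named numeric, per-clone VAF at time 0.
#' @param vafT Named numeric, per-clone VAF at time `years`.
#' @param years Follow-up span in years.
#' @param detection_limit VAF floor substituted for exact zeros.
#' @return Named numeric vector of selection coefficients (per year).
#' @export
patient1_selection_coeffs <- function(vaf0 = c(cloneA = 0.43, cloneB = 0.046),
                                      vafT = c(cloneA = 0.0, cloneB = 0.41),
                                      years = 14,
                                      detection_limit = 0.001) {
  stopifnot(length(vaf0) == length(vafT), years > 0)
  vafT <- pmax(vafT, detection_limit)
  f0 <- 2 * vaf0
  fT <- 2 * vafT
  w0 <- 1 - sum(f0)
  wT <- 1 - sum(fT)
  if (w0 <= 0 || wT <= 0) stop("cell fractions exceed 1; VAFs inconsistent")
  s <- (log(fT / wT) - log(f0 / w0)) / years
  names(s) <- names(vaf0)
  s
}

#' Default planted splicing-event truth table
#'
#' Builds the planted-event table used by [simulate_junction_counts()]:
#' cryptic events with low control PSI that shift upward in one or both
#' mutant clones, plus null events spanning the PSI range.  Planted shifts
#' default to +15 PSI points, well clear of the 2-point classification
#' threshold; truth labels follow the same rule the classifier applies
#' (both clones shifted > 2 with the same sign = common; one shifted > 2
#' with the other < 2 = biased; neither = null).
#'
#' Event types cycle through A3SS (most frequent, the hallmark lesion of
#' SF3B1-mutant cells), SE, A5SS, RI and MXE.  Cryptic-site offsets
#' alternate between frame-preserving (multiples of 3) and frameshifting
#' values, and a fraction of events is placed outside the annotated CDS to
#' exercise the noncoding consequence call.
#'
#' @param n_common,n_a_biased,n_b_biased,n_null Event counts per class.
#' @param shift Planted dPSI (percentage points) for non-null events.
#' @param psi_control Control (normal marrow) PSI for cryptic events.
#' @return A data.frame, one row per planted event.
#' @export
default_event_truth <- function(n_common = 20, n_a_biased = 15,
                                n_b_biased = 15, n_null = 50,
                                shift = 15, psi_control = 5) {
  n <- n_common + n_a_biased + n_b_biased + n_null
  lab <- c(rep("common", n_common), rep("A-biased", n_a_biased),
           rep("B-biased", n_b_biased), rep("null", n_null))
  types <- rep(c("A3SS", "SE", "A3SS", "A5SS", "RI", "MXE"), length.out = n)
  ctrl <- rep(psi_control, n)
  # null events also probe mid/high constitutive PSI levels
  ctrl[lab == "null"] <- rep(c(psi_control, 50, 90), length.out = n_null)
  psiA <- ctrl + ifelse(lab %in% c("common", "A-biased"), shift, 0)
  psiB <- ctrl + ifelse(lab %in% c("common", "B-biased"), shift, 0)
  offs <- rep(c(15L, 14L, 18L, 16L, 21L, 20L), length.out = n)
  offs[types == "SE"] <- rep(c(201L, 200L), length.out = sum(types == "SE"))
  noncoding <- seq_len(n) %% 10 == 0
  data.frame(
    event_id = sprintf("EV%03d", seq_len(n)),
    event_type = types,
    psi_control = ctrl,
    psi_cloneA = psiA,
    psi_cloneB = psiB,
    truth_label = lab,
    offset = offs,
    noncoding = noncoding,
    stringsAsFactors = FALSE
  )
}

#' Validate a planted-event table
#'
#' Checks PSI bounds and that each `truth_label` is consistent with the
#' planted dPSIs under the 2-point rule used downstream.
#'
#' @param events data.frame as produced by [default_event_truth()].
#' @param threshold Classification threshold in PSI points (default 2).
#' @return The validated table, invisibly.
#' @export
validate_event_truth <- function(events, threshold = 2) {
  need <- c("event_id", "event_type", "psi_control", "psi_cloneA",
            "psi_cloneB", "truth_label")
  if (!all(need %in% names(events)))
    stop("event truth table missing columns: ",
         paste(setdiff(need, names(events)), collapse = ", "))
  psis <- unlist(events[c("psi_control", "psi_cloneA", "psi_cloneB")])
  if (any(psis < 0 | psis > 100)) stop("planted PSI outside [0,100]")
  if (anyDuplicated(events$event_id)) stop("duplicate event ids")
  dA <- events$psi_cloneA - events$psi_control
  dB <- events$psi_cloneB - events$psi_control
  expect <- ifelse(abs(dA) > threshold & abs(dB) > threshold & sign(dA) == sign(dB),
                   "common",
            ifelse(abs(dA) > threshold & abs(dB) < threshold, "A-biased",
            ifelse(abs(dB) > threshold & abs(dA) < threshold, "B-biased",
            ifelse(abs(dA) < threshold & abs(dB) < threshold, "null",
                   "indeterminate"))))
  bad <- events$truth_label != expect
  if (any(bad))
    stop("truth_label inconsistent with planted dPSIs for: ",
         paste(events$event_id[bad], collapse = ", "))
  invisible(events)
}

#' Simulation configuration for dual-clone synthetic datasets
#'
#' Collects every generative parameter of the synthetic study: two mutant
#' clones competing against wild type under replicator dynamics, sampled
#' longitudinally with droplet-digital PCR noise; sorted-compartment
#' colony-forming assays with multinomial genotype draws and Poisson
#' mutation accrual along each clone's trunk; and single-cell splice
#' junction counts with planted common and clone-biased PSI shifts.
#'
#' Defaults are the study conditions of the index case: a 14-year
#' follow-up (12 visits), 10,000 droplets per assay, selection
#' coefficients solved from the reported endpoint VAFs, a somatic mutation
#' rate of 18/yr, ~100 colonies per sorted compartment, 100 cells per
#' genotyped clone at ~50 reads of coverage per splicing event, and 3
#' normal-bone-marrow control donors.
#'
#' @param seed Master seed (mandatory); all stage seeds derive from it via
#'   [derive_seed()].
#' @param selection_coeffs Named per-clone fitness per year, relative to
#'   wild type (s = 0).
#' @param initial_fractions Named per-clone cell fraction at time 0; the
#'   remainder is wild type.
#' @param sampling_times Months post diagnosis of the VAF visits.
#' @param droplets_per_assay ddPCR droplets counted per visit.
#' @param detection_limit ddPCR VAF floor; observed values below it are
#'   flagged censored.
#' @param compartments Named list of per-clone cell-fraction vectors, one
#'   per sorted compartment (remainder wild type).
#' @param colonies_per_compartment Colonies genotyped per compartment.
#' @param colony_sampling_month Visit (months post diagnosis) at which
#'   colonies are grown; sets donor age together with `age_at_diagnosis`.
#' @param mutation_rate_per_year Somatic mutation accrual rate (per year).
#' @param age_at_diagnosis Donor age in years at time 0.
#' @param acquisition_bounds Uniform bounds (years of age) for clone
#'   founding times when `acquisition_times` is `NULL`.
#' @param acquisition_times Optional fixed per-clone founding ages.
#' @param event_truth Planted splicing events ([default_event_truth()]).
#' @param cells_per_clone Cells per genotyped group in the junction
#'   simulation.
#' @param n_control_donors Number of normal-marrow control donors.
#' @param include_wt_cells Emit a wild-type patient cell group as well.
#' @param mean_event_coverage Mean total reads per event per cell.
#' @param coverage_dispersion Negative-binomial size of per-cell coverage.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              selection_coeffs = patient1_selection_coeffs(),
                              initial_fractions = c(cloneA = 0.86, cloneB = 0.092),
                              sampling_times = round(seq(0, 168, length.out = 12)),
                              droplets_per_assay = 10000L,
                              detection_limit = 0.001,
                              compartments = list(
                                HSC = c(cloneA = 0.40, cloneB = 0.25),
                                MPP = c(cloneA = 0.05, cloneB = 0.85)),
                              colonies_per_compartment = 100L,
                              colony_sampling_month = 23,
                              mutation_rate_per_year = 18,
                              age_at_diagnosis = 64,
                              acquisition_bounds = c(1, 50),
                              acquisition_times = NULL,
                              event_truth = default_event_truth(),
                              cells_per_clone = 100L,
                              n_control_donors = 3L,
                              include_wt_cells = TRUE,
                              mean_event_coverage = 50,
                              coverage_dispersion = 5) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(is.numeric(seed), length(seed) == 1L)
  k <- length(selection_coeffs)
  if (k < 1L) stop("need at least one mutant clone")
  if (is.null(names(selection_coeffs)))
    names(selection_coeffs) <- paste0("clone", LETTERS[seq_len(k)])
  if (length(initial_fractions) != k)
    stop("initial_fractions must match selection_coeffs in length")
  names(initial_fractions) <- names(selection_coeffs)
  if (any(initial_fractions < 0) || sum(initial_fractions) > 1)
    stop("initial_fractions must be nonnegative and sum to <= 1")
  if (is.unsorted(sampling_times, strictly = TRUE))
    stop("sampling_times must be strictly increasing")
  if (droplets_per_assay < 1) stop("droplets_per_assay must be positive")
  for (nm in names(compartments)) {
    fr <- compartments[[nm]]
    if (length(fr) != k || any(fr < 0) || sum(fr) > 1 + 1e-9)
      stop("compartment '", nm, "' clone fractions invalid")
    names(compartments[[nm]]) <- names(selection_coeffs)
  }
  if (colonies_per_compartment < 0) stop("negative colony count")
  if (mutation_rate_per_year < 0) stop("mutation rate must be >= 0")
  if (!is.null(acquisition_times)) {
    if (length(acquisition_times) != k) stop("need one acquisition time per clone")
    if (any(acquisition_times < 0 | acquisition_times > age_at_diagnosis))
      stop("acquisition times must lie in [0, age_at_diagnosis]")
  }
  if (mean_event_coverage < 0 || coverage_dispersion <= 0)
    stop("coverage parameters must be positive")
  validate_event_truth(event_truth)
  structure(list(
    seed = as.integer(seed),
    clones = names(selection_coeffs),
    selection_coeffs = selection_coeffs,
    initial_fractions = initial_fractions,
    sampling_times = sampling_times,
    droplets_per_assay = as.integer(droplets_per_assay),
    detection_limit = detection_limit,
    compartments = compartments,
    colonies_per_compartment = as.integer(colonies_per_compartment),
    colony_sampling_month = colony_sampling_month,
    mutation_rate_per_year = mutation_rate_per_year,
    age_at_diagnosis = age_at_diagnosis,
    acquisition_bounds = acquisition_bounds,
    acquisition_times = acquisition_times,
    event_truth = event_truth,
    cells_per_clone = as.integer(cells_per_clone),
    n_control_donors = as.integer(n_control_donors),
    include_wt_cells = include_wt_cells,
    mean_event_coverage = mean_event_coverage,
    coverage_dispersion = coverage_dispersion
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:", length(x$clones), "mutant clones (",
      paste(x$clones, collapse = ", "), ") + WT\n")
  cat("  s/yr:", paste(sprintf("%s=%.3f", x$clones, x$selection_coeffs),
                       collapse = ", "), "\n")
  cat("  visits:", length(x$sampling_times), "over",
      max(x$sampling_times), "months;", x$droplets_per_assay, "droplets\n")
  cat("  compartments:", paste(names(x$compartments), collapse = ", "),
      "x", x$colonies_per_compartment, "colonies\n")
  cat("  mutation rate:", x$mutation_rate_per_year, "/yr; age at dx:",
      x$age_at_diagnosis, "\n")
  cat("  planted events:", nrow(x$event_truth), "; cells/clone:",
      x$cells_per_clone, "; coverage:", x$mean_event_coverage, "\n")
  invisible(x)
}
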