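#' Aggregate single-cell junction counts into genotype pseudobulk
#'
#' Sums counts over cells within each genotype group.  Mutant clones
#' collapse to one row each; control donors keep separate rows (their
#' labels already encode the donor).  Column sums are preserved.
#'
#' @param table A [junction_count_table()] of cells.
#' @param genotypes Optional named vector overriding the table's labels
#'   (`names` = cell ids); every cell must receive a label.
#' @return A [junction_count_table()] with one row per genotype group.
#' @export
pseudobulk_by_genotype <- function(table, genotypes = NULL) {
  stopifnot(inherits(table, "junction_count_table"))
  g <- table$cells$genotype
  if (!is.null(genotypes)) {
    idx <- match(table$cells$cell_id, names(genotypes))
    if (anyNA(idx)) stop("unknown genotype label: cells without a label")
    g <- unname(genotypes[idx])
  }
  if (anyNA(g)) stop("unknown genotype label")
  agg <- rowsum(table$counts, group = g, reorder = TRUE)
  junction_count_table(agg, table$junctions, rownames(agg))
}

#' Percent spliced-in for one event across table rows
#'
#' `PSI = 100 x inclusion / (inclusion + exclusion)` per row, where each
#' side is summarized as the mean count over that side's junctions (equal
#' to the plain count for single-junction sides).  Rows whose summed
#' event coverage is below `min_coverage` are reported missing.
#'
#' @param event A [splice_event()].
#' @param table A [junction_count_table()] (cells or pseudobulk).
#' @param min_coverage Minimum inclusion + exclusion support per row.
#' @return data.frame with `group`, `psi` (percent or `NA`), `coverage`.
#' @export
compute_psi <- function(event, table, min_coverage = 10) {
  stopifnot(inherits(event, "splice_event"),
            inherits(table, "junction_count_table"))
  side <- function(ids) {
    hit <- match(ids, colnames(table$counts))
    m <- table$counts[, hit[!is.na(hit)], drop = FALSE]
    if (ncol(m) == 0) rep(0, nrow(table$counts)) else rowMeans(m)
  }
  inc <- side(event$inclusion$junction_id)
  exc <- side(event$exclusion$junction_id)
  cov <- inc + exc
  psi <- ifelse(cov >= min_coverage & cov > 0, 100 * inc / cov, NA_real_)
  data.frame(group = rownames(table$counts), psi = psi, coverage = cov,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' PSI table for a set of events
#'
#' @param events List of [splice_event()]s.
#' @param table A [junction_count_table()] (typically pseudobulk).
#' @param min_coverage Per-event, per-row coverage threshold.
#' @return Matrix events x groups of PSI percentages (`NA` below
#'   coverage), with a `"coverage"` attribute of matching shape.
#' @export
psi_table <- function(events, table, min_coverage = 10) {
  res <- lapply(events, compute_psi, table = table,
                min_coverage = min_coverage)
  groups <- res[[1]]$group
  psi <- do.call(rbind, lapply(res, function(d) d$psi))
  cov <- do.call(rbind, lapply(res, function(d) d$coverage))
  ids <- vapply(events, `[[`, "", "event_id")
  dimnames(psi) <- dimnames(cov) <- list(ids, groups)
  attr(psi, "coverage") <- cov
  psi
}

#' Per-clone dPSI against the control-donor mean
#'
#' `dPSI = PSI(clone) - mean(per-donor control PSI)`, each donor subject
#' to the coverage threshold already applied in the PSI table; missing
#' values propagate (all-missing controls give missing dPSI).
#'
#' @param psi PSI matrix from [psi_table()] (events x groups).
#' @param clone_groups Column names of the two mutant clones.
#' @param control_groups Column names of the control donors.
#' @return data.frame of `dpsi_records`: `event_id`, `dpsi_cloneA`,
#'   `dpsi_cloneB`, `clone_clone_dpsi` (A - B).
#' @export
compute_dpsi <- function(psi, clone_groups = c("cloneA", "cloneB"),
                         control_groups = grep("^control",
                                               colnames(psi), value = TRUE)) {
  if (length(control_groups) < 1) stop("need >= 1 control donor column")
  stopifnot(all(clone_groups %in% colnames(psi)))
  ctrl <- rowMeans(psi[, control_groups, drop = FALSE], na.rm = TRUE)
  ctrl[!is.finite(ctrl)] <- NA_real_
  dA <- psi[, clone_groups[1]] - ctrl
  dB <- if (length(clone_groups) > 1) psi[, clone_groups[2]] - ctrl
        else rep(NA_real_, nrow(psi))
  data.frame(event_id = rownames(psi), dpsi_cloneA = unname(dA),
             dpsi_cloneB = unname(dB),
             clone_clone_dpsi = unname(dA - dB),
             stringsAsFactors = FALSE)
}

#' Classify events as common, clone-biased, indeterminate or null
#'
#' Applies the fixed dPSI thresholds used for cryptic-event calling:
#' an event is *common* when both clones shift by more than
#' `common_threshold` PSI points (by default also requiring the same
#' direction), *X-biased* when clone X shifts by more than
#' `common_threshold` while the other clone's |dPSI| stays below
#' `bias_threshold`, *null* when both |dPSI| stay strictly below the
#' thresholds, and *indeterminate* otherwise (boundary values, opposite
#' signs under the concordance rule, or missing dPSI).  A
#' `within_band` flag marks events with |clone/clone dPSI| below `band`.
#'
#' @param records data.frame from [compute_dpsi()].
#' @param common_threshold dPSI magnitude both clones must exceed
#'   (percent; default 2).
#' @param bias_threshold dPSI magnitude the other clone must stay below
#'   for a biased call (percent; default 2).
#' @param require_sign_concordance Require same-direction shifts for
#'   "common" (default TRUE; set FALSE for a magnitude-only rule).
#' @param band |clone/clone dPSI| threshold for the `within_band` flag
#'   (default 10).
#' @return `records` with added `classification` and `within_band`.
#' @export
filter_events <- function(records, common_threshold = 2, bias_threshold = 2,
                          require_sign_concordance = TRUE, band = 10) {
  stopifnot(all(c("dpsi_cloneA", "dpsi_cloneB") %in% names(records)))
  aA <- abs(records$dpsi_cloneA)
  aB <- abs(records$dpsi_cloneB)
  same_sign <- sign(records$dpsi_cloneA) == sign(records$dpsi_cloneB)
  cls <- rep("indeterminate", nrow(records))
  ok <- !is.na(aA) & !is.na(aB)
  bigA <- ok & aA > common_threshold
  bigB <- ok & aB > common_threshold
  smallA <- ok & aA < bias_threshold
  smallB <- ok & aB < bias_threshold
  cls[bigA & bigB & (same_sign | !require_sign_concordance)] <- "common"
  cls[bigA & smallB] <- "A-biased"
  cls[bigB & smallA] <- "B-biased"
  cls[ok & aA < common_threshold & aB < common_threshold &
        aA < bias_threshold & aB < bias_threshold] <- "null"
  records$classification <- cls
  records$within_band <- abs(records$clone_clone_dpsi) < band
  records
}
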