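# Geometry templates for planted events.  Each event gets its own "gene"
# on chr1 at base B = 10000 * index, plus strand, with a fixed four-exon
# scaffold: e1 [B, B+200), e2 [B+500, ...), e3 [B+1000, B+1200),
# e4 [B+1500, B+1700).  Per-type geometry (A3SS/A5SS cryptic shift, SE
# cassette length, RI intron length, MXE exon-length difference) is
# controlled by the planted `offset` so frame-consequence truth follows
# from the same number.
.event_geometry <- function(truth_row, index) {
  B <- 10000 * index
  type <- truth_row$event_type
  d <- truth_row$offset
  e2 <- c(B + 500, B + 700)
  if (type == "A3SS") {
    inc <- junction_record("chr1", B + 200, B + 500 - d)
    exc <- junction_record("chr1", B + 200, B + 500)
  } else if (type == "A5SS") {
    inc <- junction_record("chr1", B + 200 - d, B + 500)
    exc <- junction_record("chr1", B + 200, B + 500)
  } else if (type == "SE") {
    e2 <- c(B + 500, B + 500 + d)
    inc <- junction_record("chr1", c(B + 200, e2[2]), c(e2[1], B + 1000))
    exc <- junction_record("chr1", B + 200, B + 1000)
  } else if (type == "RI") {
    e2 <- c(B + 200 + d, B + 200 + d + 200)
    exc <- junction_record("chr1", B + 200, B + 200 + d)
    inc <- junction_record("chr1", B + 200, B + 200 + d,
                           kind = "intron_proxy")
  } else if (type == "MXE") {
    e3 <- c(B + 1000, B + 1200 + d)
    inc <- junction_record("chr1", c(B + 200, e2[2]), c(e2[1], B + 1500))
    exc <- junction_record("chr1", c(B + 200, e3[2]), c(e3[1], B + 1500))
  } else stop("unknown event type: ", type)
  exons <- rbind(c(B, B + 200), e2,
                 if (type == "MXE") c(B + 1000, B + 1200 + d)
                 else c(B + 1000, B + 1200),
                 c(B + 1500, B + 1700))
  cds_span <- if (isTRUE(truth_row$noncoding)) c(B + 50, B + 150)
              else c(B + 50, B + 1650)
  gene <- paste0("g_", truth_row$event_id)
  tx <- paste0("t_", truth_row$event_id)
  ann <- data.frame(chrom = "chr1", start = exons[, 1], end = exons[, 2],
                    strand = "+", feature = "exon", gene_id = gene,
                    transcript_id = tx, stringsAsFactors = FALSE)
  cds <- ann[ann$start < cds_span[2] & ann$end > cds_span[1], , drop = FALSE]
  if (nrow(cds)) {
    cds$feature <- "CDS"
    cds$start <- pmax(cds$start, cds_span[1])
    cds$end <- pmin(cds$end, cds_span[2])
    ann <- rbind(ann, cds)
  }
  ev <- splice_event(truth_row$event_id, gene, inc, exc, annotation = ann,
                     event_type = truth_row$event_type)
  list(event = ev, annotation = ann)
}

#' Build splice events and annotation from a planted-event truth table
#'
#' @param event_truth Table from [default_event_truth()].
#' @return List with `events` (list of [splice_event()]s), `junctions`
#'   (combined junction table) and `annotation` (exon/CDS table, 0-based
#'   half-open).
#' @export
build_event_set <- function(event_truth) {
  validate_event_truth(event_truth)
  geoms <- lapply(seq_len(nrow(event_truth)), function(i)
    .event_geometry(event_truth[i, ], i))
  events <- lapply(geoms, `[[`, "event")
  names(events) <- event_truth$event_id
  annotation <- do.call(rbind, lapply(geoms, `[[`, "annotation"))
  rownames(annotation) <- NULL
  junctions <- do.call(rbind, lapply(events, function(e)
    rbind(e$inclusion, e$exclusion)))
  rownames(junctions) <- NULL
  junctions <- junctions[!duplicated(junctions$junction_id), ]
  list(events = events, junctions = junctions, annotation = annotation)
}

#' Simulate per-cell splice-junction counts with planted PSI shifts
#'
#' For every cell and planted event, total event coverage is drawn
#' negative-binomially (`mu = mean_event_coverage`, `size =
#' coverage_dispersion`) and inclusion reads binomially at the group's
#' true PSI; every inclusion junction of the event receives the inclusion
#' count and every exclusion junction the remainder, so the per-side mean
#' estimator used by [compute_psi()] is unbiased.  Cell groups are the
#' mutant clones, optionally patient wild-type cells, and
#' `n_control_donors` normal-marrow donors (all controls at the planted
#' control PSI).
#'
#' @param config A [simulation_config()].
#' @return List with `table` (a [junction_count_table()]), `events`,
#'   `annotation`, and `truth` (planted table, per-group true PSI, seed).
#' @export
simulate_junction_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (nrow(config$event_truth) == 0) stop("event truth table is empty")
  set.seed(derive_seed(config$seed, "junctions"))
  es <- build_event_set(config$event_truth)
  truth <- config$event_truth
  groups <- c(config$clones,
              if (config$include_wt_cells) "WT",
              paste0("control", seq_len(config$n_control_donors)))
  psi_of <- function(group, i) {
    if (group == config$clones[1]) truth$psi_cloneA[i]
    else if (length(config$clones) > 1 && group == config$clones[2])
      truth$psi_cloneB[i]
    else truth$psi_control[i]
  }
  n_cells <- config$cells_per_clone
  cell_ids <- unlist(lapply(groups, function(g)
    sprintf("%s_%03d", g, seq_len(n_cells))))
  genotype <- rep(groups, each = n_cells)
  counts <- matrix(0L, length(cell_ids), nrow(es$junctions),
                   dimnames = list(cell_ids, es$junctions$junction_id))
  psi_true <- matrix(NA_real_, nrow(truth), length(groups),
                     dimnames = list(truth$event_id, groups))
  for (i in seq_len(nrow(truth))) {
    ev <- es$events[[truth$event_id[i]]]
    inc_cols <- match(ev$inclusion$junction_id, colnames(counts))
    exc_cols <- match(ev$exclusion$junction_id, colnames(counts))
    for (g in seq_along(groups)) {
      psi <- psi_of(groups[g], i)
      psi_true[i, g] <- psi
      rows <- which(genotype == groups[g])
      cov <- stats::rnbinom(length(rows), size = config$coverage_dispersion,
                            mu = config$mean_event_coverage)
      k <- stats::rbinom(length(rows), cov, psi / 100)
      counts[rows, inc_cols] <- counts[rows, inc_cols] + k
      counts[rows, exc_cols] <- counts[rows, exc_cols] + (cov - k)
    }
  }
  tab <- junction_count_table(counts, es$junctions, genotype)
  list(table = tab, events = es$events, annotation = es$annotation,
       truth = list(events = truth, psi_true = psi_true,
                    groups = groups, seed = config$seed))
}
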