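#' Run the simulate -> dynamics -> phylo -> splice pipeline
#'
#' Generates a synthetic dual-clone dataset from `config`, writes every
#' intermediate file in its declared format under `outdir`, runs the
#' downstream analyses (competition fit and inversion detection, colony
#' enrichment against twice the contemporaneous bulk VAF, clone
#' clustering, perfect phylogeny with molecular-clock dating of each
#' driver, pseudobulk PSI/dPSI with event classification and consequence
#' annotation) and writes a JSON report.  Re-running with the same config
#' and seed reproduces byte-identical analytic outputs.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if absent).
#' @param stages Character subset of
#'   `c("simulate", "dynamics", "phylo", "splice")`; `simulate` is always
#'   required.
#' @param n_boot Bootstrap replicates for the competition fit.
#' @return The report list, invisibly; files under `outdir`.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "dynamics", "phylo",
                                    "splice"),
                         n_boot = 0L) {
  stopifnot(inherits(config, "simulation_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  report <- list(seed = config$seed,
                 package_version = as.character(utils::packageVersion("sf3b1clones")),
                 stages = list())
  seed <- config$seed

  traj <- simulate_clonal_trajectories(config)
  cols <- simulate_colonies(config)
  jx <- simulate_junction_counts(config)
  write_vaf_csv(traj$vaf, file.path(outdir, "vaf.csv"), seed)
  write_colony_tsv(cols$genotypes, file.path(outdir, "colonies.tsv"), seed)
  if (ncol(cols$matrix$matrix) <= 5000) {
    write_mutation_matrix_tsv(cols$matrix,
                              file.path(outdir, "mutation_matrix.tsv"), seed)
  } else {
    # study-scale private-mutation counts make the dense TSV impractical;
    # emit the sparse triplet form instead
    tr <- Matrix::summary(cols$matrix$matrix)
    .write_table(data.frame(colony = cols$matrix$colonies[tr$i],
                            variant = cols$matrix$variants[tr$j]),
                 file.path(outdir, "mutation_matrix_triplets.tsv"),
                 "mutation_matrix_triplets", seed, sep = "\t")
  }
  write_junction_counts(jx$table, file.path(outdir, "junctions"), seed)
  write_annotation_gtf(jx$annotation, file.path(outdir, "annotation.gtf"))
  report$stages$simulate <- list(
    n_visits = length(config$sampling_times),
    n_colonies = nrow(cols$genotypes),
    n_cells = nrow(jx$table$counts),
    n_events = nrow(config$event_truth))

  if ("dynamics" %in% stages) {
    fit <- fit_competition_model(traj$vaf, config$detection_limit,
                                 n_boot = n_boot, seed = seed)
    sA <- split(traj$vaf, traj$vaf$variant)
    inv <- if (length(sA) >= 2)
      detect_inversion(sA[[config$clones[1]]], sA[[config$clones[2]]])
    else NA_real_
    # enrichment: dominant clone of each compartment vs 2 x bulk VAF at
    # the colony-sampling visit
    near <- which.min(abs(traj$vaf$time_months[traj$vaf$variant ==
                                                 config$clones[1]] -
                            config$colony_sampling_month))
    enr <- lapply(names(config$compartments), function(comp) {
      gg <- cols$genotypes[cols$genotypes$compartment == comp, ]
      dom <- names(which.max(table(gg$clone[gg$clone != "WT"])))
      if (is.null(dom) || length(dom) == 0) return(NULL)
      bulk <- traj$vaf$vaf[traj$vaf$variant == dom][near]
      r <- colony_enrichment_test(sum(gg$clone == dom), nrow(gg),
                                  min(1, vaf_to_cell_fraction(bulk)),
                                  alternative = "greater")
      list(compartment = comp, clone = dom, k = r$k_clone, n = r$n_total,
           expected_fraction = r$expected_fraction, p_value = r$p_value)
    })
    dyn <- list(selection_coeffs = as.list(round(fit$s, 6)),
                selection_se = as.list(round(fit$se, 6)),
                initial_fractions = as.list(round(fit$initial_fractions, 6)),
                rss = fit$rss, inversion_month = inv,
                enrichment = enr)
    write_json_report(dyn, file.path(outdir, "dynamics.json"), seed)
    report$stages$dynamics <- dyn
  }

  if ("phylo" %in% stages) {
    cl <- cluster_colonies(cols$matrix)
    tree <- build_clone_tree(cols$matrix)
    writeLines(clone_tree_newick(tree), file.path(outdir, "clone_tree.nwk"))
    burden <- mutation_burden(cols$matrix)
    rate <- estimate_mutation_rate(burden, cols$genotypes$age_years)
    age <- cols$genotypes$age_years[1]
    dating <- do.call(rbind, lapply(config$clones, function(clname)
      date_acquisition(tree, rate$rate[1], paste0("driver_", clname), age)))
    utils::write.table(.fmt_num(dating), file.path(outdir, "age_intervals.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    report$stages$phylo <- list(
      n_clones_found = length(setdiff(unique(cl$clone),
                                      c("WT", "ambiguous"))),
      mutation_rate = rate$rate[1],
      rate_ci = c(rate$lower[1], rate$upper[1]),
      age_intervals = dating)
  }

  if ("splice" %in% stages) {
    pb <- pseudobulk_by_genotype(jx$table)
    psi <- psi_table(jx$events, pb)
    ctrl <- grep("^control", colnames(psi), value = TRUE)
    rec <- compute_dpsi(psi, clone_groups = config$clones[1:2],
                        control_groups = ctrl)
    rec <- filter_events(rec)
    rec$consequence <- vapply(jx$events[rec$event_id], annotate_consequence,
                              "", annotation = jx$annotation)
    rec$event_type <- vapply(jx$events[rec$event_id], `[[`, "",
                             "event_type")
    .write_table(rec, file.path(outdir, "dpsi_records.tsv"), "dpsi", seed,
                 sep = "\t")
    utils::write.table(.fmt_num(as.data.frame(psi)),
                       file.path(outdir, "psi_table.tsv"), sep = "\t",
                       quote = FALSE)
    report$stages$splice <- list(
      n_events = nrow(rec),
      classification = as.list(table(rec$classification)),
      truth_agreement = mean(rec$classification ==
                               jx$truth$events$truth_label))
  }

  report$runtime_seconds <- as.numeric(difftime(Sys.time(), t0,
                                                units = "secs"))
  write_json_report(report, file.path(outdir, "report.json"), seed)
  invisible(report)
}
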