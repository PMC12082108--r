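#!/usr/bin/env Rscript
# Stage 1: generate the synthetic dual-clone study dataset.
#
# Emulates the index case: two SF3B1-mutant clones competing against
# wild type over 14 years of ddPCR follow-up (selection coefficients
# solved from the printed endpoint VAFs), sorted HSC/MPP colony assays
# with clock-like mutation accrual at 18/yr, and genotyped single-cell
# splice-junction counts with planted common and clone-biased cryptic
# events.  Everything downstream (02-04) reads these files.

suppressPackageStartupMessages(library(sf3b1clones))

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
cfg <- simulation_config(seed = 1)

message("Simulating VAF trajectories: ", length(cfg$sampling_times),
        " visits, ", cfg$droplets_per_assay, " droplets each")
traj <- simulate_clonal_trajectories(cfg)
write_vaf_csv(traj$vaf, "results/data/vaf.csv", seed = cfg$seed)

message("Simulating colony assays: ",
        cfg$colonies_per_compartment, " colonies x ",
        length(cfg$compartments), " compartments, mutation rate ",
        cfg$mutation_rate_per_year, "/yr")
cols <- simulate_colonies(cfg)
write_colony_tsv(cols$genotypes, "results/data/colonies.tsv",
                 seed = cfg$seed)
message("  clone founding ages (truth): ",
        paste(sprintf("%s = %.1f y", names(cols$truth$acquisition_ages),
                      cols$truth$acquisition_ages), collapse = ", "))

message("Simulating junction counts: ", nrow(cfg$event_truth),
        " planted events x ", cfg$cells_per_clone, " cells/group")
jx <- simulate_junction_counts(cfg)
write_junction_counts(jx$table, "results/data/junctions", seed = cfg$seed)
write_annotation_gtf(jx$annotation, "results/data/annotation.gtf")

message("Done: results/data/ (vaf.csv, colonies.tsv, junctions.*, ",
        "annotation.gtf); colony mutation matrix is regenerated from ",
        "seed ", cfg$seed, " by 03_phylogeny.R")
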