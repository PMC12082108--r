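# sf3b1clones

Analysis toolkit for bone marrow carrying **two co-resident
SF3B1-mutant clones** — the rare constellation in myelodysplastic
syndrome with ring sideroblasts (MDS-RS) where two spliceosome-mutant
clones compete inside one patient, removing genetic background as a
confounder when comparing the mutations.  The package covers the four
quantitative questions such a case poses, and ships a seeded
synthetic-data generator so the entire workflow runs and is testable
without access to patient data.

## What it computes

**Clonal competition.**  Clone fractions follow replicator dynamics
with wild type as the s = 0 reference,

    df_i/dt = f_i (s_i − Σ_j f_j s_j),    VAF_i = f_i / 2  (het. diploid),

solved in closed form as normalized exponential weights.
`fit_competition_model()` estimates per-clone selection coefficients
s_i (per year) from longitudinal ddPCR VAF series with binomial droplet
noise and censoring at the detection floor; `detect_inversion()`
locates the visit-interpolated time at which the clones swap dominance.

**Colony enrichment.**  `colony_enrichment_test()` is the exact
binomial tail test of k clone colonies among n genotyped
colony-forming units against a null fraction of twice the bulk VAF
(the heterozygous-diploid cell fraction).

**Clone phylogeny and molecular-clock dating.**
`build_clone_tree()` reconstructs the perfect phylogeny from a binary
colony × variant matrix by nested carrier-set containment (explicit
three-gamete check), `estimate_mutation_rate()` fits burden ~ rate ×
age through the origin, and `date_acquisition()` converts trunk
mutation counts into acquisition-age intervals with exact Poisson 95%
bounds clamped to the donor's age.

**Genotype-aware splicing.**  `pseudobulk_by_genotype()`,
`psi_table()` and `compute_dpsi()` turn per-cell splice-junction
counts into per-clone percent-spliced-in (PSI = 100·inc/(inc+exc)) and
dPSI against the mean of normal-marrow control donors;
`classify_event()` types events (SE, A3SS, A5SS, RI, MXE) from
junction geometry; `filter_events()` applies the fixed 2-point
thresholds (common: both clones |dPSI| > 2; clone-biased: the other
clone < 2); `annotate_consequence()` reports in-frame vs frameshift vs
noncoding from the cryptic-site offset within the annotated CDS.

## Worked example

```r
library(sf3b1clones)

# study-shaped synthetic dataset: two clones, 12 visits over 14 years
cfg  <- simulation_config(seed = 1)
traj <- simulate_clonal_trajectories(cfg)
fit  <- fit_competition_model(traj$vaf, n_boot = 200, seed = 1)
fit
#> competition fit (replicator model, WT s = 0):
#>   cloneA: s = -0.5288 /yr (se 0.0090), f0 = 0.8604
#>   cloneB: s = 0.0590 /yr (se 0.0061), f0 = 0.0925
#>   rss = 0.000302, convergence = 0

sv <- split(traj$vaf, traj$vaf$variant)
detect_inversion(sv$cloneA, sv$cloneB)
#> [1] 45.54545   # months post diagnosis at which the clones swap

# the worked colony statistic: 105/121 progenitor colonies vs
# a null of twice the 27% bulk VAF
colony_enrichment_test(105, 121, vaf_to_cell_fraction(0.27), "greater")
#> colony enrichment: 105/121 vs expected 0.540 (greater): p = 1.39e-14
```

The fitted coefficients say clone A is collapsing at ~0.53/yr against
wild type while clone B gains ~0.06/yr, reproducing the inversion the
defaults were solved from (43% → 0% vs 4.6% → 41% VAF); the
enrichment p-value shows progenitor colonies are far more often
mutant than bulk VAF predicts.

A full narrated pass over one simulated study — trajectories, colony
assays, phylogeny with dated drivers, PSI/dPSI classification — is in
the numbered drivers:

```sh
Rscript analysis/01_simulate.R     # writes results/data/
Rscript analysis/02_competition.R  # fit, inversion, enrichment tests
Rscript analysis/03_phylogeny.R    # clone tree, rate, age intervals
Rscript analysis/04_splicing.R     # PSI/dPSI, classification, frames
```

Their summary tables land under `results/`.  The methods vignette
(`vignettes/dual-clone-analysis.Rmd`) documents the models,
assumptions, defaults and known limitations.

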