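test_that("identical seeds give bit-identical outputs from every generator", {
  cfg <- small_config(seed = 11)
  a1 <- simulate_clonal_trajectories(cfg)
  a2 <- simulate_clonal_trajectories(cfg)
  expect_identical(a1, a2)
  b1 <- simulate_colonies(cfg)
  b2 <- simulate_colonies(cfg)
  expect_identical(b1$matrix$matrix, b2$matrix$matrix)
  expect_identical(b1$genotypes, b2$genotypes)
  c1 <- simulate_junction_counts(cfg)
  c2 <- simulate_junction_counts(cfg)
  expect_identical(c1$table$counts, c2$table$counts)
  # different seed actually changes the draws
  b3 <- simulate_colonies(small_config(seed = 12))
  expect_false(identical(b1$genotypes$clone, b3$genotypes$clone))
})

test_that("clone fractions stay in the simplex; equal fitness freezes them", {
  for (seed in 1:5) {
    set.seed(seed)
    k <- sample(1:3, 1)
    s <- stats::runif(k, -0.6, 0.6)
    f0 <- stats::runif(k); f0 <- f0 / sum(f0) * stats::runif(1, 0.2, 0.95)
    names(s) <- names(f0) <- paste0("clone", LETTERS[1:k])
    f <- clone_fractions(seq(0, 20, by = 0.5), s, f0)
    expect_true(all(f >= 0 & f <= 1))
    expect_equal(unname(rowSums(f)), rep(1, nrow(f)))
  }
  # symmetry: no fitness differences (mutants at the WT reference rate)
  # leave every fraction constant
  f <- clone_fractions(0:15, c(a = 0, b = 0), c(a = 0.3, b = 0.1))
  expect_equal(f, f[rep(1, nrow(f)), ], ignore_attr = TRUE)
  # equally fit mutants keep a constant ratio to each other
  f2 <- clone_fractions(0:15, c(a = 0.2, b = 0.2), c(a = 0.3, b = 0.1))
  expect_equal(f2[, "a"] / f2[, "b"], rep(3, 16))
})

test_that("deterministic trajectories match the closed-form two-type logistic", {
  s <- c(cloneA = 0.05, cloneB = 0.25)
  f0 <- c(cloneA = 0.2, cloneB = 0.05)
  cfg <- simulation_config(seed = 5, selection_coeffs = s,
                           initial_fractions = f0)
  out <- simulate_clonal_trajectories(cfg)
  oracle <- two_clone_logistic_oracle(cfg$sampling_times / 12, s, f0)
  vafA <- out$truth$vaf_true$vaf[out$truth$vaf_true$variant == "cloneA"]
  vafB <- out$truth$vaf_true$vaf[out$truth$vaf_true$variant == "cloneB"]
  expect_lt(max(abs(vafA - oracle[, "A"] / 2)), 1e-6)
  expect_lt(max(abs(vafB - oracle[, "B"] / 2)), 1e-6)
  # droplet sampling concentrates on the deterministic path
  obs <- out$vaf$vaf[out$vaf$variant == "cloneB"]
  expect_lt(max(abs(obs - vafB)), 0.02)
})

test_that("patient-shaped defaults reproduce a clonal frequency inversion", {
  cfg <- simulation_config(seed = 7)
  out <- simulate_clonal_trajectories(cfg)
  tr <- out$truth$vaf_true
  a <- tr[tr$variant == "cloneA", c("time_months", "vaf")]
  b <- tr[tr$variant == "cloneB", c("time_months", "vaf")]
  expect_gt(a$vaf[1], b$vaf[1])            # A starts dominant
  expect_lt(a$vaf[nrow(a)], b$vaf[nrow(b)])  # B ends dominant
  cross <- detect_inversion(a, b)
  expect_false(is.na(cross))
  expect_gt(cross, 0)
  expect_lt(cross, 168)
  # endpoints sit at the reported values the defaults were solved from
  expect_equal(a$vaf[1], 0.43, tolerance = 1e-6)
  expect_equal(b$vaf[nrow(b)], 0.41, tolerance = 1e-3)
})

test_that("colony genotype draws are multinomial: chi-square GOF across seeds", {
  probs <- c(cloneA = 0.40, cloneB = 0.25, WT = 0.35)
  pass <- 0
  for (rep in 1:100) {
    cfg <- simulation_config(seed = 1000 + rep,
                             compartments = list(HSC = probs[1:2]),
                             colonies_per_compartment = 60L,
                             mutation_rate_per_year = 0.1)
    co <- simulate_colonies(cfg)
    counts <- table(factor(co$genotypes$clone, levels = names(probs)))
    p <- suppressWarnings(stats::chisq.test(counts, p = probs)$p.value)
    if (p > 0.01) pass <- pass + 1
  }
  expect_gte(pass, 95)
})

test_that("trunk mutations are exactly clone-partitioned in the matrix", {
  cfg <- small_config(seed = 21)
  co <- simulate_colonies(cfg)
  m <- as.matrix(co$matrix$matrix)
  for (cl in cfg$clones) {
    trunk <- co$truth$trunk[[cl]]
    in_clone <- co$genotypes$clone == cl
    # every colony of the clone carries the full trunk
    expect_true(all(m[in_clone, trunk] == 1))
    # no colony outside the clone carries any of it
    expect_true(all(m[!in_clone, trunk] == 0))
  }
  # clone fraction 1.0 makes every colony that clone
  cfg2 <- simulation_config(seed = 22, compartments = list(
    MEP = c(cloneA = 0, cloneB = 1)), colonies_per_compartment = 15L,
    mutation_rate_per_year = 1)
  co2 <- simulate_colonies(cfg2)
  expect_true(all(co2$genotypes$clone == "cloneB"))
  # negative colony count is rejected at configuration time
  expect_error(simulation_config(seed = 1, colonies_per_compartment = -3L),
               "negative")
})

test_that("pooled PSI falls inside the exact binomial interval of truth", {
  cfg <- simulation_config(seed = 31)  # defaults: 100 cells, coverage 50
  jx <- simulate_junction_counts(cfg)
  pb <- pseudobulk_by_genotype(jx$table)
  psi <- psi_table(jx$events, pb)
  cov <- attr(psi, "coverage")
  truth <- jx$truth$psi_true
  inside <- 0; total <- 0
  for (g in c("cloneA", "cloneB")) {
    for (i in seq_len(nrow(psi))) {
      n <- round(cov[i, g]); p <- truth[rownames(psi)[i], g] / 100
      lo <- 100 * stats::qbinom(0.025, n, p) / n
      hi <- 100 * stats::qbinom(0.975, n, p) / n
      total <- total + 1
      if (psi[i, g] >= lo && psi[i, g] <= hi) inside <- inside + 1
    }
  }
  expect_gte(inside / total, 0.93)
})

test_that("degenerate PSI truth and junction geometry behave as declared", {
  truth <- data.frame(event_id = c("E1", "E2"), event_type = "A3SS",
                      psi_control = c(100, 0), psi_cloneA = c(100, 0),
                      psi_cloneB = c(100, 0), truth_label = "null",
                      offset = 15L, noncoding = FALSE)
  cfg <- simulation_config(seed = 41, event_truth = truth,
                           cells_per_clone = 30L)
  jx <- simulate_junction_counts(cfg)
  ev1 <- jx$events[["E1"]]
  exc_cols <- ev1$exclusion$junction_id
  expect_true(all(jx$table$counts[, exc_cols] == 0))  # psi 100: no exclusion
  ev2 <- jx$events[["E2"]]
  expect_true(all(jx$table$counts[, ev2$inclusion$junction_id] == 0))
  # planted A3SS junctions share the donor (intron start) coordinate
  expect_equal(ev1$inclusion$start, ev1$exclusion$start)
  expect_equal(ev1$inclusion$strand, "+")
  # PSI outside [0,100] is rejected
  bad <- truth; bad$psi_cloneA <- c(120, 0)
  expect_error(simulation_config(seed = 1, event_truth = bad), "PSI")
})
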