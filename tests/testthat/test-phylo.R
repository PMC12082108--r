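test_that("colonies cluster into clones by shared trunks; WT has none", {
  # two disjoint trunks of 3 and 2 variants, one wild-type colony
  m <- matrix(0L, 5, 6,
              dimnames = list(paste0("c", 1:5),
                              c("t1a", "t1b", "t1c", "t2a", "t2b", "pX")))
  m[1:2, c("t1a", "t1b", "t1c")] <- 1L
  m[3:4, c("t2a", "t2b")] <- 1L
  m[5, "pX"] <- 0L
  cl <- cluster_colonies(m)
  expect_equal(cl$clone[1], cl$clone[2])
  expect_equal(cl$clone[3], cl$clone[4])
  expect_false(cl$clone[1] == cl$clone[3])
  expect_equal(cl$clone[5], "WT")
  expect_false(any(cl$ambiguous))
})

test_that("cluster_colonies recovers simulated truth, exactly then gracefully", {
  cfg <- simulation_config(seed = 51, colonies_per_compartment = 40L,
                           mutation_rate_per_year = 2)
  co <- simulate_colonies(cfg)
  cl <- cluster_colonies(co$matrix)
  truth <- co$genotypes$clone
  # map discovered clone labels to truth by majority vote
  tab <- table(cl$clone, truth)
  acc <- sum(apply(tab, 1, max)) / length(truth)
  expect_gte(acc, 0.99)
  # inject ~1% genotyping error into the trunk columns and tolerate it
  set.seed(52)
  m <- as.matrix(co$matrix$matrix)
  flip <- sample(length(m), round(0.01 * length(m)))
  m[flip] <- 1L - m[flip]
  cl2 <- cluster_colonies(m)
  tab2 <- table(cl2$clone, truth)
  acc2 <- sum(apply(tab2, 1, max)) / length(truth)
  expect_gte(acc2, 0.90)
})

test_that("nested carrier sets build a single chain", {
  m <- matrix(0L, 4, 3, dimnames = list(paste0("c", 1:4), c("A", "B", "C")))
  m[1:4, "A"] <- 1L; m[2:4, "B"] <- 1L; m[4, "C"] <- 1L
  tree <- build_clone_tree(m)
  nd <- tree$nodes
  expect_equal(nd$parent[nd$id == "A"], "root")
  expect_equal(nd$parent[nd$id == "B"], "A")
  expect_equal(nd$parent[nd$id == "C"], "B")
  # variants with identical carrier sets merge lexicographically
  m2 <- cbind(m, D = m[, "B"])
  tree2 <- build_clone_tree(m2)
  expect_equal(tree2$mutations[["B"]], c("B", "D"))
  expect_equal(tree2$nodes$n_mutations[tree2$nodes$id == "B"], 2L)
})

test_that("the forbidden gamete pattern raises an incompatibility error", {
  m <- matrix(c(1, 0, 1,
                0, 1, 1), ncol = 2,
              dimnames = list(c("c1", "c2", "c3"), c("vA", "vB")))
  expect_false(isTRUE(three_gamete_check(m)))
  err <- tryCatch(build_clone_tree(m), error = identity)
  expect_s3_class(err, "incompatibility_error")
  expect_match(conditionMessage(err), "vA|vB")
  expect_setequal(err$pair, c("vA", "vB"))
})

test_that("reconstruction equals exhaustive enumeration on random matrices", {
  set.seed(61)
  for (i in 1:60) {
    m <- random_pp_matrix(sample(2:6, 1), sample(3:8, 1))
    en <- pp_enumerate(m)
    expect_equal(length(en$valid), 1L)
    pm <- impl_parent_map(m)
    om <- oracle_parent_map(en)
    expect_identical(pm[order(names(pm))], om[order(names(om))])
  }
})

test_that("missing entries are uninformative, not reference calls", {
  m <- matrix(c(1, 1, 1,
                1, 1, NA,
                0, 0, 1), ncol = 3, byrow = FALSE,
              dimnames = list(paste0("c", 1:3), c("A", "B", "C")))
  tree <- build_clone_tree(m)
  # c3 not genotyped for B: B's observed carriers are c1,c2, a strict
  # subset of A's, so B stays a separate child branch (treating NA as a
  # carrier would merge it into A's trunk)
  expect_equal(tree$nodes$parent[tree$nodes$id == "B"], "A")
  expect_equal(tree$mutations[["B"]], "B")
  mm <- mutation_matrix(m)
  expect_equal(nrow(mm$missing), 1L)
  expect_error(mutation_matrix(matrix(NA, 1, 2)), "all entries missing")
})

test_that("Newick round trip preserves topology and mutation counts", {
  cfg <- simulation_config(seed = 71, colonies_per_compartment = 10L,
                           mutation_rate_per_year = 1)
  co <- simulate_colonies(cfg)
  tree <- build_clone_tree(co$matrix)
  phy <- ape::read.tree(text = clone_tree_newick(tree))
  expect_setequal(phy$tip.label, tree$colonies$colony)
  expect_equal(sum(phy$edge.length), sum(tree$nodes$n_mutations))
  # root-to-tip path length = colony burden (trunk + private mutations)
  depth <- ape::node.depth.edgelength(phy)
  burden <- mutation_burden(co$matrix)
  expect_equal(depth[seq_along(phy$tip.label)],
               unname(burden[phy$tip.label]))
})

test_that("mutation rate estimation matches clock arithmetic and glm", {
  expect_equal(estimate_mutation_rate(60, 30)$rate, 2.0)
  b <- c(10, 20, 30); a <- c(5, 10, 15)
  expect_equal(estimate_mutation_rate(b, a)$rate, 2.0)  # exact linear case
  # independent route: Poisson regression through the origin via glm offset
  set.seed(81)
  ages <- stats::runif(25, 20, 70)
  burd <- stats::rpois(25, 18 * ages)
  r <- estimate_mutation_rate(burd, ages)
  g <- stats::glm(burd ~ 1 + offset(log(ages)), family = stats::poisson())
  expect_equal(r$rate, unname(exp(stats::coef(g))), tolerance = 1e-8)
  expect_error(estimate_mutation_rate(c(3, 4), c(0, 0)), "all ages zero")
  # stratified estimates are grouped independently
  rs <- estimate_mutation_rate(c(b, 60), c(a, 30),
                               groups = c("wt", "wt", "wt", "mt"))
  expect_equal(rs$rate[rs$group == "mt"], 2.0)
})

test_that("rate confidence intervals cover the truth across replicates", {
  cover <- 0
  set.seed(91)
  for (rep in 1:100) {
    ages <- stats::runif(20, 30, 70)
    burd <- stats::rpois(20, 18 * ages)
    r <- estimate_mutation_rate(burd, ages)
    if (r$lower <= 18 && 18 <= r$upper) cover <- cover + 1
  }
  expect_gte(cover, 90)
})

test_that("acquisition dating bounds behave as a molecular clock", {
  # driver on the first trunk branch: lower bound 0
  m <- matrix(0L, 4, 4,
              dimnames = list(paste0("c", 1:4),
                              c("drv", "t1", "s1", "s2")))
  m[1:3, c("drv", "t1")] <- 1L
  m[2:3, "s1"] <- 1L
  m[3, "s2"] <- 1L
  tree <- build_clone_tree(m)
  ai <- date_acquisition(tree, rate = 2, driver = "drv",
                         age_at_sampling = 60)
  expect_equal(ai$lower_bound_years, 0)
  expect_lte(ai$upper_bound_years, 60)
  expect_true(ai$lower_bound_years <= ai$point_estimate_years &&
                ai$point_estimate_years <= ai$upper_bound_years)
  # a subclonal driver has ancestral mutations: both bounds move up
  ai2 <- date_acquisition(tree, rate = 2, driver = "s1",
                          age_at_sampling = 60)
  expect_gt(ai2$lower_bound_years, 0)
  expect_gte(ai2$upper_bound_years, ai$upper_bound_years)
  ai3 <- date_acquisition(tree, rate = 2, driver = "s2",
                          age_at_sampling = 60)
  expect_gte(ai3$lower_bound_years, ai2$lower_bound_years)
  expect_gte(ai3$point_estimate_years, ai2$point_estimate_years)
  # clamping: tiny rate pushes the raw upper bound past the donor age
  ai4 <- date_acquisition(tree, rate = 0.01, driver = "drv",
                          age_at_sampling = 60)
  expect_equal(ai4$upper_bound_years, 60)
  expect_error(date_acquisition(tree, 2, "absent", 60), "absent")
})
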