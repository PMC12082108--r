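# Independent oracles and fixture builders shared across the suite.

# Brute-force binomial tail probability from first principles
# (choose() products, no pbinom), the reference for the exact test.
binom_tail_oracle <- function(k, n, p, alternative = "greater") {
  pmf <- vapply(0:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), 0)
  upper <- sum(pmf[k:n + 1])
  lower <- sum(pmf[0:k + 1])
  switch(alternative,
         greater = upper,
         less = lower,
         two.sided = min(1, 2 * min(lower, upper)))
}

# Independent closed form for the two-type competition trajectory:
# each clone's odds against wild type grow exponentially at its own rate,
# and fractions are recovered from the odds (no call into the package).
two_clone_logistic_oracle <- function(t_years, s, f0) {
  odds0 <- f0 / (1 - sum(f0))
  oddsA <- odds0[1] * exp(s[1] * t_years)
  oddsB <- odds0[2] * exp(s[2] * t_years)
  cbind(A = oddsA / (1 + oddsA + oddsB), B = oddsB / (1 + oddsA + oddsB))
}

# Random matrix guaranteed compatible with a perfect phylogeny: built by
# planting variants on a random rooted tree and sampling colonies from
# its nodes.
random_pp_matrix <- function(n_var, n_col) {
  parent <- integer(n_var)
  for (v in seq_len(n_var)) parent[v] <- sample(0:(v - 1), 1)
  anc <- function(v) {
    out <- integer(0)
    while (v != 0) { out <- c(out, v); v <- parent[v] }
    out
  }
  m <- matrix(0L, n_col, n_var,
              dimnames = list(sprintf("c%02d", seq_len(n_col)),
                              sprintf("v%02d", seq_len(n_var))))
  for (c0 in seq_len(n_col)) {
    node <- sample(0:n_var, 1)
    if (node > 0) m[c0, anc(node)] <- 1L
  }
  m
}

# Exhaustive enumeration of perfect phylogenies for a small 0/1 matrix:
# tries every parent assignment over carrier-set groups (candidates
# restricted to strict supersets, which loses no valid tree) and keeps
# those where each colony's containing groups form exactly its
# root-path.  Returns every valid parent vector.
pp_enumerate <- function(mat) {
  carriers <- lapply(seq_len(ncol(mat)), function(j) which(mat[, j] == 1))
  keep <- lengths(carriers) > 0
  carriers <- carriers[keep]
  vars <- colnames(mat)[keep]
  sig <- vapply(carriers, paste, "", collapse = ",")
  grp <- split(seq_along(carriers), sig)
  labels <- vapply(grp, function(ix) sort(vars[ix])[1], "")
  sets <- lapply(grp, function(ix) carriers[[ix[1]]])
  G <- length(sets)
  if (G == 0) return(list(valid = list(integer(0)), labels = labels))
  cand <- lapply(seq_len(G), function(g)
    c(0L, which(vapply(seq_len(G), function(h)
      h != g && length(sets[[g]]) < length(sets[[h]]) &&
        all(sets[[g]] %in% sets[[h]]), TRUE))))
  valid <- list()
  rec <- function(g, parent) {
    if (g > G) {
      for (c0 in seq_len(nrow(mat))) {
        contain <- which(vapply(seq_len(G), function(h)
          c0 %in% sets[[h]], TRUE))
        if (length(contain) == 0) next
        start <- contain[which.min(lengths(sets)[contain])]
        path <- integer(0); cur <- start
        while (cur != 0L) { path <- c(path, cur); cur <- parent[cur] }
        if (!setequal(path, contain)) return(invisible(NULL))
      }
      valid[[length(valid) + 1L]] <<- parent
      return(invisible(NULL))
    }
    for (p in cand[[g]]) { parent[g] <- p; rec(g + 1L, parent) }
  }
  rec(1L, integer(G))
  list(valid = valid, labels = labels, sets = sets)
}

# child -> parent label map of the package's tree, for oracle comparison
impl_parent_map <- function(mat) {
  tree <- build_clone_tree(mat)
  nd <- tree$nodes[tree$nodes$id != "root", , drop = FALSE]
  stats::setNames(nd$parent, nd$id)
}

oracle_parent_map <- function(en, which = 1) {
  stats::setNames(vapply(en$valid[[which]], function(p)
    if (p == 0) "root" else en$labels[p], ""), en$labels)
}

# Patient-shaped two-visit VAF fixture built from the reported endpoints:
# clone A 43% -> 0% and clone B 4.6% -> 41% over 168 months.
patient_endpoint_fixture <- function() {
  data.frame(
    variant = rep(c("cloneA", "cloneB"), each = 2),
    time_months = c(0, 168, 0, 168),
    vaf = c(0.43, 0, 0.046, 0.41),
    droplets = 10000L,
    censored = c(FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

# small, fast config for structural tests
small_config <- function(seed, ...) {
  simulation_config(seed = seed, colonies_per_compartment = 20L,
                    mutation_rate_per_year = 2,
                    cells_per_clone = 20L,
                    event_truth = default_event_truth(4, 3, 3, 5), ...)
}
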