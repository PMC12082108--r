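#' Assign colonies to clones from shared trunk mutations
#'
#' Candidate trunk variants are those carried by at least
#' `max(2, 5% of colonies)` colonies: genuine trunk mutations are shared
#' by every sampled colony of their clone, while sporadic genotyping
#' errors on the vast private-mutation background produce spurious
#' 2-3-carrier columns that this threshold removes.  Each colony is then
#' summarized by its shared-variant set.
#' Colonies whose sets overlap substantially (at least `min_shared`
#' variants and Jaccard similarity at least `similarity`) are linked, and
#' the connected components with two or more members define the clones.
#' Each clone's consensus trunk is the set of variants carried by at
#' least half of its member colonies, which discards sporadic genotyping
#' errors while tolerating dropout.  Colonies are then assigned to every
#' trunk they match in at least `max(min_shared, half the trunk)`
#' variants: no match labels the colony `WT`, exactly one assigns the
#' clone, two or more flags it `ambiguous` rather than failing.
#'
#' @param mm A [mutation_matrix()] (or plain 0/1 matrix with optional
#'   `NA`).
#' @param min_shared Minimum trunk variants a colony must share to join a
#'   clone (default 1; trunks in this setting carry the driver plus 1-4
#'   co-mutations).
#' @param similarity Minimum Jaccard similarity of shared-variant sets
#'   for two colonies to be linked (default 0.3).
#' @return data.frame with `colony`, `clone` (`"clone1"`, ... by
#'   decreasing size, `"WT"`, or `"ambiguous"`), and `ambiguous` flag.
#' @export
cluster_colonies <- function(mm, min_shared = 1L, similarity = 0.3) {
  if (!inherits(mm, "mutation_matrix")) mm <- mutation_matrix(mm)
  if (nrow(mm$matrix) == 0) stop("empty mutation matrix")
  carriers <- .carrier_sets(mm)
  n <- nrow(mm$matrix)
  min_carriers <- max(2, ceiling(0.05 * n))
  shared_vars <- names(carriers)[lengths(carriers) >= min_carriers]
  per_colony <- vector("list", n)
  for (v in shared_vars)
    for (i in carriers[[v]]) per_colony[[i]] <- c(per_colony[[i]], v)
  # single-linkage over Jaccard similarity of shared-variant sets
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nonempty <- which(lengths(per_colony) > 0)
  for (a in seq_along(nonempty)) {
    i <- nonempty[a]
    for (b in seq_len(a - 1L)) {
      j <- nonempty[b]
      ov <- length(intersect(per_colony[[i]], per_colony[[j]]))
      if (ov < min_shared) next
      un <- length(per_colony[[i]]) + length(per_colony[[j]]) - ov
      if (ov / un >= similarity) parent[find(i)] <- find(j)
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  comps <- split(seq_len(n), comp)
  comps <- comps[lengths(comps) >= 2]
  # consensus trunk: variants in >= half of the component's colonies
  trunks <- lapply(comps, function(ix) {
    tab <- table(unlist(per_colony[ix]))
    names(tab)[tab >= length(ix) / 2]
  })
  trunks <- trunks[lengths(trunks) >= min_shared]
  clone <- rep("WT", n)
  amb <- rep(FALSE, n)
  if (length(trunks)) {
    hits <- vapply(trunks, function(tr) vapply(per_colony, function(s)
      sum(s %in% tr), 0L), integer(n))
    hits <- matrix(hits, nrow = n)
    need <- pmax(min_shared, ceiling(lengths(trunks) / 2))
    compat <- sweep(hits, 2, need, `>=`)
    match_ct <- rowSums(compat)
    one <- which(match_ct == 1)
    assign_ti <- max.col(compat[one, , drop = FALSE], ties.method = "first")
    sizes <- tabulate(assign_ti, nbins = length(trunks))
    ord <- order(-sizes, vapply(trunks, function(tr) sort(tr)[1], ""))
    clone[one] <- paste0("clone", match(assign_ti, ord))
    amb[match_ct >= 2] <- TRUE
    clone[match_ct >= 2] <- "ambiguous"
  }
  data.frame(colony = mm$colonies, clone = clone, ambiguous = amb,
             stringsAsFactors = FALSE)
}

#' Check the three-gamete (perfect phylogeny) condition
#'
#' Two variants are incompatible when their observed carrier sets are
#' neither nested nor disjoint, i.e. the colony x 2-variant submatrix
#' contains the (0,1), (1,0) and (1,1) rows.  Missing entries are
#' uninformative and excluded.
#'
#' @param mm A [mutation_matrix()] (or plain matrix).
#' @return `TRUE` if compatible; otherwise an attribute-carrying `FALSE`
#'   with `attr(,"pair")` naming an offending variant pair.
#' @export
three_gamete_check <- function(mm) {
  if (!inherits(mm, "mutation_matrix")) mm <- mutation_matrix(mm)
  groups <- .carrier_groups(mm)
  sets <- lapply(groups, `[[`, "carriers")
  for (i in seq_along(sets)) {
    for (j in seq_len(i - 1L)) {
      ov <- length(intersect(sets[[i]], sets[[j]]))
      if (ov > 0 && ov < min(length(sets[[i]]), length(sets[[j]]))) {
        res <- FALSE
        attr(res, "pair") <- c(groups[[i]]$variants[1],
                               groups[[j]]$variants[1])
        return(res)
      }
    }
  }
  TRUE
}

# variants grouped by identical observed carrier sets; variants with no
# observed carrier are dropped (recorded in attr "unplaced")
.carrier_groups <- function(mm) {
  carriers <- .carrier_sets(mm)
  keep <- lengths(carriers) > 0
  carriers <- carriers[keep]
  sig <- vapply(carriers, paste, "", collapse = ",")
  idx <- split(names(carriers), sig)
  groups <- lapply(idx, function(vars) {
    vars <- sort(vars)
    list(variants = vars, carriers = carriers[[vars[1]]],
         label = vars[1], n = length(vars))
  })
  # deterministic order: decreasing carrier-set size, then label
  ord <- order(-vapply(groups, function(g) length(g$carriers), 0L),
               vapply(groups, `[[`, "", "label"))
  structure(groups[ord], unplaced = names(keep)[!keep])
}

#' Reconstruct a perfect phylogeny from a binary mutation matrix
#'
#' Variants with identical observed carrier sets merge onto one branch
#' (ordered lexicographically by id); branches nest by strict carrier-set
#' containment, which exists and is unique exactly when the three-gamete
#' condition holds.  Colonies attach below the smallest carrier set
#' containing them; colonies carrying no placed variant attach at the
#' root (wild type).  Branch length is the number of merged variants.
#'
#' @param mm A [mutation_matrix()] (or plain 0/1 matrix, `NA` = missing).
#' @return Object of class `clone_tree`: `nodes` (data.frame `id`,
#'   `parent`, `label`, `n_mutations`), `mutations` (per-node variant
#'   sets), `colonies` (attachment of each colony).
#' @export
build_clone_tree <- function(mm) {
  if (!inherits(mm, "mutation_matrix")) mm <- mutation_matrix(mm)
  tg <- three_gamete_check(mm)
  if (!isTRUE(tg)) {
    pair <- attr(tg, "pair")
    stop(structure(class = c("incompatibility_error", "error", "condition"),
                   list(message = paste0(
                     "three-gamete condition violated by variants '",
                     pair[1], "' and '", pair[2], "'"),
                     call = sys.call(), pair = pair)))
  }
  groups <- .carrier_groups(mm)
  G <- length(groups)
  sizes <- vapply(groups, function(g) length(g$carriers), 0L)
  parent <- integer(G)  # 0 = root
  if (G > 0) for (g in seq_len(G)) {
    best <- 0L; best_size <- Inf
    for (h in seq_len(G)) {
      if (h == g) next
      if (sizes[h] > sizes[g] && all(groups[[g]]$carriers %in%
                                     groups[[h]]$carriers) &&
          sizes[h] < best_size) {
        best <- h; best_size <- sizes[h]
      }
    }
    parent[g] <- best
  }
  labels <- vapply(groups, `[[`, "", "label")
  parent_label <- vapply(parent, function(p)
    if (p == 0L) "root" else labels[p], "")
  nodes <- data.frame(
    id = c("root", labels),
    parent = c(NA_character_, parent_label),
    label = c("root", labels),
    n_mutations = c(0L, vapply(groups, `[[`, 0L, "n")),
    stringsAsFactors = FALSE)
  mutations <- c(list(root = character(0)),
                 stats::setNames(lapply(groups, `[[`, "variants"),
                                 vapply(groups, `[[`, "", "label")))
  # attach colonies below the smallest containing group
  att <- rep("root", nrow(mm$matrix))
  for (ci in seq_len(nrow(mm$matrix))) {
    containing <- which(vapply(groups, function(g) ci %in% g$carriers, TRUE))
    if (length(containing)) {
      sm <- containing[which.min(sizes[containing])]
      att[ci] <- groups[[sm]]$label
    }
  }
  structure(list(nodes = nodes,
                 mutations = mutations,
                 colonies = data.frame(colony = mm$colonies, node = att,
                                       stringsAsFactors = FALSE),
                 unplaced_variants = attr(groups, "unplaced")),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("clone_tree:", nrow(x$nodes) - 1L, "branches,",
      nrow(x$colonies), "colonies,",
      sum(x$nodes$n_mutations), "placed mutations\n")
  invisible(x)
}

#' Convert a clone tree to an ape `phylo` object
#'
#' Colonies become tips; every internal branch's length is its mutation
#' count (colony tip edges have length 0) and internal node labels carry
#' the branch's representative mutation id.
#'
#' @param x A `clone_tree`.
#' @param ... Unused.
#' @return An object of class `phylo`.
#' @export
as_phylo <- function(x, ...) UseMethod("as_phylo")

#' @rdname as_phylo
#' @export
as_phylo.clone_tree <- function(x, ...) {
  tips <- x$colonies$colony
  internal <- x$nodes$id
  n_tip <- length(tips)
  if (n_tip < 2) stop("need >= 2 colonies for a phylo conversion")
  node_num <- stats::setNames(n_tip + seq_along(internal), internal)
  edges <- list(); lens <- numeric(0)
  for (i in seq_len(nrow(x$nodes))) {
    if (is.na(x$nodes$parent[i])) next
    edges[[length(edges) + 1]] <- c(node_num[[x$nodes$parent[i]]],
                                    node_num[[x$nodes$id[i]]])
    lens <- c(lens, x$nodes$n_mutations[i])
  }
  for (i in seq_len(nrow(x$colonies))) {
    edges[[length(edges) + 1]] <- c(node_num[[x$colonies$node[i]]], i)
    lens <- c(lens, 0)
  }
  phy <- structure(list(edge = do.call(rbind, edges),
                        edge.length = lens,
                        tip.label = tips,
                        node.label = internal,
                        Nnode = length(internal)),
                   class = "phylo", order = "cladewise")
  phy
}

#' Serialize a clone tree to a Newick string
#'
#' @param tree A `clone_tree`.
#' @return Newick string (branch lengths = mutation counts).
#' @export
clone_tree_newick <- function(tree) {
  ape::write.tree(as_phylo(tree))
}
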